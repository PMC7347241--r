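# Self-tuning spectral clustering of one VJ(l)-group: junction/CDR3 Hamming
# distance X, combination with the SHM similarity S into a weighted distance
# W, per-sequence local scales from a density-gap search, Gaussian kernel K,
# unnormalised Laplacian L = D - K, eigen-gap model selection for the number
# of clones k, and k-means over the first k eigenvectors.

#' Junction/CDR3 Hamming distance matrix
#'
#' Pairwise Hamming distances between the members' junction sequences
#' (`target = "junction"`) or their CDR3s, i.e. the junction minus the
#' three-nucleotide prefix and suffix (`target = "cdr3"`). Positions where
#' either sequence has a non-ACGT character are not counted (ambiguity never
#' inflates distance). CDR3 mode requires junction length >= 7; shorter
#' groups fall back to the full junction with a warning.
#'
#' @param group a `vjl_group`.
#' @param target `"junction"` or `"cdr3"`.
#' @return Symmetric integer matrix with zero diagonal.
#' @export
junction_distance_matrix <- function(group, target = c("junction", "cdr3")) {
  target <- match.arg(target)
  juncs <- group$junctions
  l <- group$junction_length
  if (target == "cdr3") {
    if (l < 7L) {
      warning("junction length ", l, " too short for CDR3 distance in group ",
              group$group_id, "; falling back to junction", call. = FALSE)
    } else {
      juncs <- substr(juncs, 4L, l - 3L)
    }
  }
  mat <- .char_matrix(juncs)
  bases <- c("A", "C", "G", "T")
  Cmat <- (mat %in% bases)
  dim(Cmat) <- dim(mat)
  valid <- tcrossprod(Cmat * 1)
  matches <- Reduce(`+`, lapply(bases, function(b) tcrossprod((mat == b) * 1)))
  X <- valid - matches
  diag(X) <- 0
  dimnames(X) <- list(group$member_ids, group$member_ids)
  X
}

#' Weighted distance matrix
#'
#' `W = X` for the recombination-based model; `W = (1 - S) * X` for the
#' integrated model, where the SHM similarity acts like a spring constant
#' pulling mutation-sharing pairs together (Hooke's-law analogy `W = kappa X`
#' with `kappa = 1 - S`).
#'
#' @param X recombination-based distance matrix.
#' @param S SHM similarity matrix (ignored for `method = "recomb"`).
#' @param method `"recomb"` or `"integrated"`.
#' @return Symmetric weighted-distance matrix with `0 <= W <= X`.
#' @export
weighted_distance <- function(X, S = NULL, method = c("recomb", "integrated")) {
  method <- match.arg(method)
  if (method == "recomb") return(X)
  if (is.null(S)) stop("integrated model needs the SHM similarity S",
                       call. = FALSE)
  (1 - S) * X
}

#' Per-sequence local scales (distance-gap procedure)
#'
#' For each row of the weighted-distance matrix, seeks a relatively large gap
#' in that sequence's distances to all others: a Gaussian kernel density
#' estimate (Silverman's rule-of-thumb bandwidth, 512-point grid over the
#' data range) is scanned for local minima (first finite difference changing
#' sign from negative to positive); among qualifying minima the one with the
#' lowest density wins (ties to the smallest location) and the scale is the
#' largest observed distance strictly below it. When no qualifying minimum
#' exists, the scale is the distance at the lower edge of the largest gap in
#' the rank-ordered distances. A zero scale is replaced by the smallest
#' positive distance of the row, or 1 if the whole row is zero.
#'
#' @param W symmetric weighted-distance matrix with at least 3 rows.
#' @return Strictly positive numeric vector of per-sequence scales.
#' @export
local_scales <- function(W) {
  m <- nrow(W)
  if (m < 3L) stop("local scaling needs at least 3 sequences", call. = FALSE)
  vapply(seq_len(m), function(i) .row_scale(W[i, -i]), numeric(1L))
}

.row_scale <- function(d) {
  w <- NA_real_
  if (length(unique(d)) >= 2L && diff(range(d)) > 1e-8 * max(1, max(d))) {
    # Silverman's rule-of-thumb bandwidth, 1.06 * sigma * n^(-1/5); unlike
    # the IQR-guarded variant it cannot collapse on near-lattice distances
    dens <- try(suppressWarnings(
      stats::density(d, bw = "nrd", n = 512L,
                     from = min(d), to = max(d))), silent = TRUE)
    if (!inherits(dens, "try-error")) {
      dy <- diff(dens$y)
      # index p is a local minimum when the slope turns negative -> positive
      minima <- which(dy[-length(dy)] < 0 & dy[-1L] > 0) + 1L
      if (length(minima) > 0L) {
        best <- minima[order(dens$y[minima], dens$x[minima])][1L]
        below <- d[d < dens$x[best]]
        if (length(below) > 0L) w <- max(below)
      }
    }
  }
  if (is.na(w)) {
    ds <- sort(d)
    gaps <- diff(ds)
    w <- if (length(gaps) == 0L || max(gaps) == 0) {
      ds[1L]
    } else {
      # lower edge of the largest gap; ties broken toward the largest
      # distance (wider neighborhood, conservative against false splits)
      ds[max(which(gaps == max(gaps)))]
    }
  }
  if (w == 0) {
    pos <- d[d > 0]
    w <- if (length(pos) > 0L) min(pos) else 1
  }
  w
}

#' Gaussian kernel matrix with local scaling
#'
#' `K[i,j] = exp(-W[i,j]^2 / (w_i * w_j))`: a fully connected graph kernel
#' whose neighbourhood width adapts per sequence.
#'
#' @param W weighted-distance matrix.
#' @param w strictly positive vector of local scales.
#' @return Symmetric kernel matrix with unit diagonal and entries in (0, 1\].
#' @export
kernel_matrix <- function(W, w) {
  if (any(w <= 0)) stop("local scales must be strictly positive", call. = FALSE)
  K <- exp(-W^2 / outer(w, w))
  diag(K) <- 1
  K
}

#' Unnormalised graph Laplacian
#'
#' `L = D - K` with `D` the diagonal degree matrix (`D_ii = sum_j K_ij`).
#' Rows sum to zero and `L` is symmetric positive semi-definite.
#'
#' @param K symmetric kernel matrix.
#' @return The Laplacian matrix.
#' @export
laplacian_matrix <- function(K) {
  diag(rowSums(K)) - K
}

#' Number of clones from the eigen-gap
#'
#' Returns the index `k` maximising the gap `lambda[k+1] - lambda[k]` of the
#' ascending Laplacian eigenvalue spectrum, breaking ties toward smaller `k`.
#'
#' @param eigenvalues eigenvalues sorted ascending.
#' @return Integer number of clusters in `[1, m]`.
#' @export
estimate_k <- function(eigenvalues) {
  m <- length(eigenvalues)
  if (m <= 1L) return(1L)
  gaps <- diff(eigenvalues)
  which.max(gaps)    # first maximum = smallest k on ties
}

# k-means++ seeding + Lloyd refinement via stats::kmeans, best of `nstart`
# restarts. Duplicated rows are collapsed first so kmeans never sees fewer
# distinct points than centers.
.kmeanspp <- function(x, k, nstart = 10L) {
  x <- as.matrix(x)
  ux <- unique(x)
  nu <- nrow(ux)
  if (k >= nu) {
    lab_u <- seq_len(nu)
  } else {
    best <- NULL
    for (s in seq_len(nstart)) {
      centers <- matrix(NA_real_, k, ncol(ux))
      centers[1L, ] <- ux[sample.int(nu, 1L), ]
      d2 <- rowSums((ux - matrix(centers[1L, ], nu, ncol(ux), byrow = TRUE))^2)
      if (k > 1L) for (c in 2L:k) {
        probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / nu, nu)
        centers[c, ] <- ux[sample.int(nu, 1L, prob = probs), ]
        d2 <- pmin(d2, rowSums((ux - matrix(centers[c, ], nu, ncol(ux),
                                            byrow = TRUE))^2))
      }
      fit <- suppressWarnings(
        try(stats::kmeans(ux, centers = centers, iter.max = 100L),
            silent = TRUE))
      if (inherits(fit, "try-error")) next
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    if (is.null(best)) {
      best <- stats::kmeans(ux, centers = min(k, nu), nstart = nstart,
                            iter.max = 100L)
    }
    lab_u <- best$cluster
  }
  key <- apply(x, 1L, paste, collapse = "\r")
  ukey <- apply(ux, 1L, paste, collapse = "\r")
  lab_u[match(key, ukey)]
}

#' Cluster one VJ(l)-group into clones
#'
#' Runs the full per-group pipeline: recombination distance `X` (plus SHM
#' similarity `S` for the integrated model), weighted distance `W`, local
#' scales, kernel, Laplacian, eigen-gap choice of `k`, and k-means over the
#' `k` eigenvectors of the smallest eigenvalues. Groups of size 1 become a
#' single clone; size-2 groups merge iff their weighted distance is exactly 0
#' (the eigen-gap is meaningless at m = 2). If the eigen-decomposition fails
#' it is retried with symmetric jitter `1e-12`; on persistent failure the
#' group falls back to the recombination-based model with a warning.
#'
#' @param group a `vjl_group`.
#' @param method `"recomb"` or `"integrated"`.
#' @param target `"junction"` or `"cdr3"`.
#' @param tm a `targeting_model` (integrated model only).
#' @param seed integer seed fixing the k-means restarts.
#' @return List with integer `labels` (one per member), `k`, and `fallback`
#'   (logical).
#' @export
cluster_group <- function(group, method = c("recomb", "integrated"),
                          target = c("junction", "cdr3"),
                          tm = NULL, seed = 1L) {
  method <- match.arg(method)
  target <- match.arg(target)
  m <- length(group$member_ids)
  if (m == 1L) return(list(labels = 1L, k = 1L, fallback = FALSE))
  if (method == "integrated" && is.null(tm)) {
    stop("integrated model needs a targeting model", call. = FALSE)
  }
  X <- junction_distance_matrix(group, target)
  S <- NULL
  if (method == "integrated") S <- .shm_matrices(group, tm, target)$S
  W <- weighted_distance(X, S, method)
  if (m == 2L) {
    labels <- if (W[1L, 2L] == 0) c(1L, 1L) else c(1L, 2L)
    return(list(labels = labels, k = max(labels), fallback = FALSE))
  }
  if (max(W) == 0) {
    return(list(labels = rep(1L, m), k = 1L, fallback = FALSE))
  }
  w <- local_scales(W)
  K <- kernel_matrix(W, w)
  L <- laplacian_matrix(K)
  # Model selection and embedding use the symmetrically normalised spectrum
  # D^(-1/2) L D^(-1/2): its eigenvalues live in [0, 2], so the eigen-gap
  # reflects the component structure of the kernel graph instead of its
  # degree spread, and block-diagonal kernels give k = number of blocks
  # regardless of block sizes.
  dinv <- 1 / sqrt(rowSums(K))
  Ln <- L * outer(dinv, dinv)
  ev <- try(eigen(Ln, symmetric = TRUE), silent = TRUE)
  if (inherits(ev, "try-error")) {
    ev <- try(eigen(Ln + diag(1e-12, m), symmetric = TRUE), silent = TRUE)
  }
  if (inherits(ev, "try-error")) {
    if (method == "integrated") {
      warning("eigen-decomposition failed for group ", group$group_id,
              "; falling back to recombination-based model", call. = FALSE)
      out <- cluster_group(group, "recomb", target, tm, seed)
      out$fallback <- TRUE
      return(out)
    }
    return(list(labels = rep(1L, m), k = 1L, fallback = TRUE))
  }
  lambda <- rev(ev$values)
  k <- estimate_k(lambda)
  if (k == 1L) return(list(labels = rep(1L, m), k = 1L, fallback = FALSE))
  vecs <- ev$vectors[, rev(seq_len(ncol(ev$vectors))), drop = FALSE]
  emb <- vecs[, seq_len(k), drop = FALSE]
  labels <- withr::with_seed(seed, .kmeanspp(emb, k))
  list(labels = as.integer(labels), k = k, fallback = FALSE)
}

# deterministic, order-independent per-group seed derived from the run seed
.group_seed <- function(group_id, seed) {
  codes <- utf8ToInt(group_id)
  h <- sum(codes * seq_along(codes)) %% 1000003L
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

#' Assign clones across a whole repertoire
#'
#' Builds VJ(l)-groups from a filtered, collapsed rearrangement set and
#' clusters every group independently (groups are embarrassingly parallel;
#' results are merged by group id, so execution order never changes the
#' partition). Clone ids are globally unique; sequences collapsed into a
#' representative inherit its clone through the set's collapse map.
#'
#' @param rs a `rearrangement_set` (ideally filtered and collapsed).
#' @param method `"recomb"` or `"integrated"`.
#' @param target `"junction"` or `"cdr3"`.
#' @param tm `targeting_model` for the integrated model (default: built-in
#'   synthetic hot-spot model).
#' @param seed integer run seed (fixes the k-means restarts).
#' @param mode VJ(l)-grouping mode, `"chain"` (default) or `"exact"`.
#' @param threads number of worker processes for per-group dispatch.
#' @return A `clone_partition`: list with `assignments` (named character,
#'   every input sequence_id including collapsed duplicates), `per_group`
#'   run report, `method`, `target`, `seed`.
#' @export
assign_clones <- function(rs, method = c("recomb", "integrated"),
                          target = c("junction", "cdr3"),
                          tm = NULL, seed = 1L,
                          mode = c("chain", "exact"), threads = 1L) {
  method <- match.arg(method)
  target <- match.arg(target)
  mode <- match.arg(mode)
  if (method == "integrated" && is.null(tm)) tm <- hotspot_targeting_model()
  groups <- build_vjl_groups(rs, mode)
  order_ids <- order(vapply(groups, `[[`, "", "group_id"))
  groups <- groups[order_ids]

  run_one <- function(group) {
    res <- cluster_group(group, method, target, tm,
                         seed = .group_seed(group$group_id, seed))
    list(group_id = group$group_id, member_ids = group$member_ids,
         m = length(group$member_ids), k = res$k, labels = res$labels,
         fallback = res$fallback)
  }
  results <- if (threads > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(groups, run_one, mc.cores = threads)
  } else {
    lapply(groups, run_one)
  }

  assignments <- character(0)
  per_group <- data.frame(group_id = character(0), m = integer(0),
                          k = integer(0), fallback = logical(0))
  offset <- 0L
  for (res in results) {
    ids <- paste0(offset + res$labels)
    names(ids) <- res$member_ids
    assignments <- c(assignments, ids)
    offset <- offset + res$k
    per_group <- rbind(per_group, data.frame(
      group_id = res$group_id, m = res$m, k = res$k, fallback = res$fallback))
  }
  cmap <- attr(rs, "collapse_map")
  if (!is.null(cmap)) {
    expanded <- assignments[unname(cmap)]
    names(expanded) <- names(cmap)
    assignments <- expanded
  }
  structure(list(assignments = assignments, per_group = per_group,
                 method = method, target = target, seed = seed,
                 config_name = paste0("ham",
                                      if (method == "integrated") "-shm",
                                      "-", if (target == "junction") "junc"
                                      else "cdr3")),
            class = "clone_partition")
}

#' @export
print.clone_partition <- function(x, ...) {
  cat(sprintf("clone partition (%s): %d sequence(s), %d clone(s), %d group(s)\n",
              x$config_name, length(x$assignments),
              length(unique(x$assignments)), nrow(x$per_group)))
  invisible(x)
}
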