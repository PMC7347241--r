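# SHM-based pairwise similarity. Within a VJ(l)-group, every sequence pair
# is compared with the group's effective germline outside the junction (or
# CDR3) span. Per-position mutation flags are classified as
#   alpha: mutated in exactly one of the two sequences,
#   beta:  mutated in both, to different bases,
#   gamma: mutated in both, to the same base (a shared mutation),
# and accumulated into a total-mutation matrix T and shared-mutation matrix
# H, normalised by the mean number of informative (ACGT) positions. Shared
# mutations at hot-spot motifs are damped by M, and T, H, M combine into the
# SHM-similarity S through group-adaptive Gaussian envelopes.

# Positions used for SHM analysis given a group and a target region.
# junction-targeted: mask out the whole junction span;
# cdr3-targeted:     mask out the junction span minus 3 nt at each end, so
#                    the conserved flanks ARE analysed for SHM.
.shm_mask <- function(group, target = c("junction", "cdr3")) {
  target <- match.arg(target)
  mask <- group$junction_mask
  if (target == "cdr3" && length(mask) > 6L) {
    mask <- mask[seq.int(4L, length(mask) - 3L)]
  }
  mask
}

#' Classify pairwise mutations against an effective germline
#'
#' Compares two aligned sequences with the effective germline of their group
#' and flags, per unmasked position, whether a mutation is unique to one
#' sequence (`alpha`), present in both with different bases (`beta`), or
#' shared (`gamma`, same substituted base in both). A sequence is mutated at
#' a position iff its base is a plain A/C/G/T that is not in the IUPAC set of
#' the germline character. Positions where either sequence has a non-ACGT
#' character, or where the germline is `N` or a gap, carry no flags. `nu` is
#' the mean of the two per-sequence counts of unmasked informative (ACGT)
#' positions.
#'
#' @param seq_i,seq_j aligned nucleotide strings of equal length.
#' @param egl effective germline (IUPAC) of the same length.
#' @param mask integer vector of alignment positions to exclude (the junction
#'   or CDR3 span).
#' @return A `mutation_profile`: list with logical vectors `alpha`, `beta`,
#'   `gamma` (full alignment length), `shared_positions`, and `nu`.
#' @export
classify_pair_mutations <- function(seq_i, seq_j, egl, mask = integer(0)) {
  if (nchar(seq_i) != nchar(seq_j) || nchar(seq_i) != nchar(egl)) {
    stop("sequences and effective germline must have equal lengths",
         call. = FALSE)
  }
  ci <- strsplit(toupper(seq_i), "", fixed = TRUE)[[1L]]
  cj <- strsplit(toupper(seq_j), "", fixed = TRUE)[[1L]]
  cg <- strsplit(toupper(egl), "", fixed = TRUE)[[1L]]
  L <- length(cg)
  informative <- !(cg == "N") & !.is_gap(cg) & (cg %in% names(.IUPAC_SETS))
  use <- informative
  if (length(mask) > 0L) use[mask] <- FALSE

  in_gl_set <- function(base, glchar) {
    mapply(function(b, g) b %in% .IUPAC_SETS[[g]], base, glchar)
  }
  acgt_i <- .is_acgt(ci); acgt_j <- .is_acgt(cj)
  mut_i <- logical(L); mut_j <- logical(L)
  sel <- use & acgt_i
  mut_i[sel] <- !in_gl_set(ci[sel], cg[sel])
  sel <- use & acgt_j
  mut_j[sel] <- !in_gl_set(cj[sel], cg[sel])

  valid <- use & acgt_i & acgt_j
  gamma <- valid & mut_i & mut_j & (ci == cj)
  beta <- valid & mut_i & mut_j & (ci != cj)
  alpha <- valid & xor(mut_i, mut_j)
  nu <- (sum(use & acgt_i) + sum(use & acgt_j)) / 2
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 shared_positions = which(gamma), nu = nu),
            class = "mutation_profile")
}

# Vectorised per-group machinery -------------------------------------------
#
# For a group of m sequences of alignment length L, build per-base mutated
# indicator matrices Mb (m x L, one per base b) and an informative indicator
# C, all restricted to unmasked positions with informative germline. Then
#   both-mutated counts = A A',         A = sum_b Mb
#   gamma counts        = sum_b Mb Mb'
#   alpha counts        = A C' + C A' - 2 (A A')
#   nu_ij               = (rowSums(C)_i + rowSums(C)_j) / 2
# which gives T and H in a handful of matrix products.

.group_indicators <- function(group, target = c("junction", "cdr3")) {
  target <- match.arg(target)
  mat <- .char_matrix(group$sequences)
  cg <- strsplit(group$effective_germline, "", fixed = TRUE)[[1L]]
  L <- length(cg)
  use <- !(cg == "N") & !.is_gap(cg) & (cg %in% names(.IUPAC_SETS))
  mask <- .shm_mask(group, target)
  if (length(mask) > 0L) use[mask] <- FALSE
  usemat <- matrix(use, nrow = nrow(mat), ncol = L, byrow = TRUE)

  bases <- c("A", "C", "G", "T")
  Cmat <- (mat == "A" | mat == "C" | mat == "G" | mat == "T") & usemat
  Mb <- lapply(bases, function(b) {
    is_b <- mat == b
    # mutated to b: base b observed and b not in the germline's IUPAC set
    gl_has_b <- vapply(cg, function(g) b %in% (.IUPAC_SETS[[g]] %||% character(0)),
                       logical(1L), USE.NAMES = FALSE)
    gl_has_b <- matrix(gl_has_b, nrow = nrow(mat), ncol = L, byrow = TRUE)
    (is_b & !gl_has_b & usemat) * 1
  })
  names(Mb) <- bases
  list(Mb = Mb, C = Cmat * 1, use = use, mat = mat)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Total- and shared-mutation matrices of a VJ(l)-group
#'
#' Computes the symmetric matrices `T` (normalised total pairwise mutation
#' count: unique mutations count once, same-position mutations twice) and
#' `H` (normalised shared mutation count) over all sequence pairs of a
#' group, against the group's effective germline, excluding the junction or
#' CDR3 span. Entries for fully uninformative pairs (`nu = 0`) are set to 0
#' with a warning.
#'
#' @param group a `vjl_group` with at least 2 members.
#' @param target `"junction"` or `"cdr3"` (controls the excluded span).
#' @return List with matrices `T`, `H`, the `nu` matrix, and the internal
#'   indicator structure reused by [damping_matrix()].
#' @export
mutation_matrices <- function(group, target = c("junction", "cdr3")) {
  target <- match.arg(target)
  ind <- .group_indicators(group, target)
  m <- length(group$sequences)
  if (m < 2L) stop("need at least 2 sequences", call. = FALSE)
  A <- Reduce(`+`, ind$Mb)
  both <- tcrossprod(A)                       # alpha+beta+gamma bookkeeping
  gammaC <- Reduce(`+`, lapply(ind$Mb, tcrossprod))
  AC <- tcrossprod(A, ind$C)
  alphaC <- AC + t(AC) - 2 * both
  betaC <- both - gammaC
  ni <- rowSums(ind$C)
  nu <- outer(ni, ni, `+`) / 2
  Tm <- matrix(0, m, m); Hm <- matrix(0, m, m)
  ok <- nu > 0
  if (any(!ok & upper.tri(nu))) {
    warning("fully uninformative sequence pair(s) in group ", group$group_id,
            call. = FALSE)
  }
  Tm[ok] <- (alphaC[ok] + 2 * (betaC[ok] + gammaC[ok])) / nu[ok]
  Hm[ok] <- 2 * gammaC[ok] / nu[ok]
  diag(Tm) <- 0; diag(Hm) <- 0
  dimnames(Tm) <- dimnames(Hm) <- list(group$member_ids, group$member_ids)
  list(T = Tm, H = Hm, nu = nu, indicators = ind)
}

#' Hot-spot damping matrix
#'
#' `M[i, j]` is the product over all positions carrying a shared mutation of
#' `1 - mu(n)`, where `mu(n)` is the motif mutability at position `n`
#' averaged over the group's distinct germline alleles. With no shared
#' mutations the empty product gives 1; high-mutability (hot-spot) shared
#' mutations are discounted because unrelated sequences are more likely to
#' acquire them independently.
#'
#' @param group a `vjl_group`.
#' @param tm a `targeting_model`.
#' @param target `"junction"` or `"cdr3"`.
#' @param indicators optional precomputed indicator structure from
#'   [mutation_matrices()].
#' @return Symmetric matrix `M` with entries in \[0, 1\] and unit diagonal.
#' @export
damping_matrix <- function(group, tm, target = c("junction", "cdr3"),
                           indicators = NULL) {
  target <- match.arg(target)
  ind <- indicators %||% .group_indicators(group, target)
  L <- length(ind$use)
  mu <- .position_mutability(tm, group$germlines, L)
  loss <- log(pmax(1 - mu, 0))                # -Inf when mu == 1
  m <- nrow(ind$C)
  acc <- matrix(0, m, m)
  for (Mb in ind$Mb) {
    scaled <- Mb * matrix(loss, m, L, byrow = TRUE)
    scaled[Mb == 0] <- 0                      # keep 0 * -Inf out
    acc <- acc + tcrossprod(Mb, scaled)
  }
  M <- exp(acc)
  diag(M) <- 1
  dimnames(M) <- list(group$member_ids, group$member_ids)
  M
}

#' SHM similarity from T, H and M
#'
#' `S[i,j] = M[i,j] * exp(-(T-H)^2 / 2 sigma_T^2) * (1 - exp(-H^2 / 2 sigma_H^2))`,
#' where `sigma_T` and `sigma_H` are the population standard deviations of
#' the off-diagonal upper-triangular entries of `T` and `H` within the group,
#' making the similarity adaptive to the group's local mutation frequency.
#' `S` is zero wherever `H` is zero: without shared mutations the
#' recombination-based distance alone drives clustering. When a standard
#' deviation is zero the Gaussian envelope degenerates to an indicator
#' (`exp(-x^2/2*0^2)` taken as 1 for `x = 0`, 0 otherwise).
#'
#' @param T,H,M conformable symmetric matrices.
#' @param sigma_T,sigma_H optional standard deviations; computed from `T`/`H`
#'   when missing.
#' @return Symmetric similarity matrix `S` with entries in \[0, 1\) and zero
#'   diagonal.
#' @export
shm_similarity <- function(T, H, M, sigma_T = NULL, sigma_H = NULL) {
  pop_sd <- function(x) {
    v <- x[upper.tri(x)]
    if (length(v) == 0L) return(0)
    sqrt(mean((v - mean(v))^2))
  }
  if (is.null(sigma_T)) sigma_T <- pop_sd(T)
  if (is.null(sigma_H)) sigma_H <- pop_sd(H)
  gauss <- function(x, s) {
    if (s > 0) return(exp(-x^2 / (2 * s^2)))
    (x == 0) * 1                              # degenerate sigma: indicator
  }
  S <- M * gauss(T - H, sigma_T) * (1 - gauss(H, sigma_H))
  S[H == 0] <- 0
  diag(S) <- 0
  S
}

# Full SHM pipeline for one group: T, H, M, S (and the sigmas used).
.shm_matrices <- function(group, tm, target = c("junction", "cdr3")) {
  target <- match.arg(target)
  th <- mutation_matrices(group, target)
  M <- damping_matrix(group, tm, target, indicators = th$indicators)
  pop_sd <- function(x) {
    v <- x[upper.tri(x)]
    sqrt(mean((v - mean(v))^2))
  }
  sT <- pop_sd(th$T); sH <- pop_sd(th$H)
  S <- shm_similarity(th$T, th$H, M, sT, sH)
  list(T = th$T, H = th$H, M = M, S = S, sigma_T = sT, sigma_H = sH)
}
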