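# Distance matrices, local scaling, kernel, Laplacian, eigen-gap, and the
# per-group and whole-repertoire clustering drivers.

test_that("junction and CDR3 Hamming distances count informative mismatches", {
  g <- make_group(c("TGTGCAAGG", "TGTGCTAGG"), "TGTGCAAGG",
                  junctions = c("TGTGCAAGG", "TGTGCTAGG"))
  expect_equal(junction_distance_matrix(g, "junction")[1, 2], 1)
  expect_equal(junction_distance_matrix(g, "cdr3")[1, 2], 1)  # GCA vs GCT

  gid <- make_group(c("TGTGCAAGG", "TGTGCAAGG"), "TGTGCAAGG")
  expect_equal(junction_distance_matrix(gid)[1, 2], 0)

  # N at a mismatching position is not counted
  gn <- make_group(c("TGTGCAAGG", "TGTGCNAGG"), "TGTGCAAGG",
                   junctions = c("TGTGCAAGG", "TGTGCNAGG"))
  expect_equal(junction_distance_matrix(gn, "junction")[1, 2], 0)

  gshort <- make_group(c("TGTTGG", "TGATGG"), "TGTTGG",
                       junctions = c("TGTTGG", "TGATGG"))
  expect_warning(X <- junction_distance_matrix(gshort, "cdr3"),
                 "falling back")
  expect_equal(X[1, 2], 1)
})

test_that("weighted distance reduces to X and scales by 1 - S", {
  X <- matrix(c(0, 4, 4, 0), 2)
  expect_equal(weighted_distance(X, method = "recomb"), X)
  expect_equal(weighted_distance(X, matrix(0, 2, 2), "integrated"), X)
  S <- matrix(c(0, 0.5, 0.5, 0), 2)
  expect_equal(weighted_distance(X, S, "integrated")[1, 2], 2)
  S9 <- matrix(c(0, 0.99, 0.99, 0), 2)
  expect_lt(weighted_distance(X, S9, "integrated")[1, 2], 0.1)
})

test_that("local scales find the density gap or fall back to rank gaps", {
  # all distances equal: the common value
  W <- matrix(2, 4, 4); diag(W) <- 0
  expect_equal(local_scales(W), rep(2, 4))

  # spec'd rank-gap fixture: sorted row [0.10, 0.15, 0.80, 0.85] -> 0.15
  expect_equal(clonespect:::.row_scale(c(0.10, 0.15, 0.80, 0.85)), 0.15)

  # two well-separated blobs: scale falls between them
  withr::with_seed(3, {
    d <- c(rnorm(40, 1, 0.05), rnorm(40, 5, 0.05))
    w <- clonespect:::.row_scale(d)
    expect_gt(w, 0.8); expect_lt(w, 2)
  })

  # an all-zero row substitutes 1
  expect_equal(clonespect:::.row_scale(rep(0, 5)), 1)
  expect_error(local_scales(matrix(0, 2, 2)), "at least 3")
})

test_that("kernel, Laplacian and eigen-gap behave per construction", {
  W <- matrix(c(0, 2, 2, 0), 2)
  K <- kernel_matrix(W, c(2, 2))
  expect_equal(K[1, 2], exp(-1))
  expect_equal(diag(K), c(1, 1))
  expect_error(kernel_matrix(W, c(0, 2)), "strictly positive")

  expect_equal(laplacian_matrix(matrix(1, 2, 2)),
               matrix(c(1, -1, -1, 1), 2))
  withr::with_seed(8, {
    A <- matrix(runif(49), 7); K2 <- (A + t(A)) / 2; diag(K2) <- 1
    L <- laplacian_matrix(K2)
    expect_equal(max(abs(rowSums(L))), 0, tolerance = 1e-12)
    expect_gt(min(eigen(L, symmetric = TRUE)$values), -1e-10)
  })

  expect_equal(estimate_k(c(0, 0.02, 0.05, 1.1, 1.2, 1.25)), 3L)
  expect_equal(estimate_k(c(0, 1, 1, 1)), 1L)
  expect_equal(estimate_k(0), 1L)
  expect_equal(estimate_k(c(0, 0.5, 1.0)), 1L)   # tie broken toward small k
})

test_that("block-diagonal kernels yield one clone per block", {
  # two blocks of unequal size, zero kernel between blocks
  blocks <- c(rep(1, 9), rep(2, 3))
  seqs <- ifelse(blocks == 1,
                 "TGTAAAAAAAAAAAAAAAAAAAAAAAAAAATGG",
                 "TGTCCCCCCCCCCCCCCCCCCCCCCCCCCCTGG")
  # add small within-block variation so the group is not fully degenerate
  seqs[2] <- sub("AAATGG$", "AATTGG", seqs[2])
  seqs[10] <- sub("CCCTGG$", "CCTTGG", seqs[10])
  g <- make_group(seqs, seqs[1], junctions = seqs)
  res <- cluster_group(g, method = "recomb", target = "junction", seed = 1)
  expect_equal(res$k, 2L)
  expect_equal(length(unique(res$labels[blocks == 1])), 1L)
  expect_equal(length(unique(res$labels[blocks == 2])), 1L)
})

test_that("degenerate groups collapse to single clones", {
  seqs <- rep("TGTAAACCCGGGTGG", 5)
  g <- make_group(seqs, seqs[1], junctions = seqs)
  res <- cluster_group(g, "recomb", "junction", seed = 1)
  expect_equal(res$k, 1L)
  expect_equal(res$labels, rep(1L, 5))
  g1 <- make_group(seqs[1], seqs[1], junctions = seqs[1])
  expect_equal(cluster_group(g1, "recomb", "junction", seed = 1)$labels, 1L)
})

test_that("size-2 groups merge only at zero weighted distance", {
  seqs <- c("TGTAAACCCGGGTGG", "TGTAAACCCGGGTGG")
  g <- make_group(seqs, seqs[1], junctions = seqs)
  expect_equal(cluster_group(g, "recomb", "junction", seed = 1)$labels,
               c(1L, 1L))
  seqs2 <- c("TGTAAACCCGGGTGG", "TGTAAACCCGTGTGG")
  g2 <- make_group(seqs2, seqs2[1], junctions = seqs2)
  expect_equal(cluster_group(g2, "recomb", "junction", seed = 1)$labels,
               c(1L, 2L))
})

test_that("integrated model equals recomb when no mutations are shared", {
  # unmutated sequences: H = 0 everywhere, so S = 0 and Eq 5 reduces
  sim <- small_sim(seed = 13, n = 80)
  raw <- sim$rearrangements
  raw$sequence_alignment <- raw$germline_alignment
  vlen <- 300L   # toy pool V length; junction starts at the last V codon
  raw$junction <- substr(raw$germline_alignment, vlen - 2L,
                         vlen - 3L + raw$junction_length)
  rs <- collapse_identical(clonespect:::.new_rearrangement_set(as.data.frame(raw)))
  pr <- assign_clones(rs, "recomb", "cdr3", seed = 5)
  pi <- assign_clones(rs, "integrated", "cdr3", seed = 5,
                      tm = hotspot_targeting_model())
  expect_equal(unname(pi$assignments[names(pr$assignments)]),
               unname(pr$assignments))
})

test_that("partitions are deterministic and order-insensitive", {
  sim <- small_sim(seed = 17, n = 100)
  rs <- collapse_identical(suppressMessages(filter_productive(sim$rearrangements)))
  p1 <- assign_clones(rs, "integrated", "cdr3", seed = 11)
  p2 <- assign_clones(rs, "integrated", "cdr3", seed = 11)
  expect_identical(p1$assignments, p2$assignments)

  # permuting input rows changes labels at most, not the induced partition
  perm <- withr::with_seed(1, sample(nrow(rs)))
  rsp <- clonespect:::.rs_attr_keep(rs, as.data.frame(rs)[perm, ])
  p3 <- assign_clones(rsp, "integrated", "cdr3", seed = 11)
  ids <- names(p1$assignments)
  part_a <- split(ids, unname(p1$assignments[ids]))
  part_b <- split(ids, unname(p3$assignments[ids]))
  norm <- function(p) sort(vapply(p, function(x)
    paste(sort(x), collapse = ","), ""))
  expect_equal(norm(part_a), norm(part_b))
})

test_that("clones never span VJ(l)-groups", {
  sim <- small_sim(seed = 19, n = 120)
  rs <- collapse_identical(suppressMessages(filter_productive(sim$rearrangements)))
  part <- assign_clones(rs, "recomb", "junction", seed = 2)
  groups <- build_vjl_groups(rs)
  group_of <- rep(vapply(groups, `[[`, "", "group_id"),
                  vapply(groups, function(g) length(g$member_ids), 0L))
  names(group_of) <- unlist(lapply(groups, `[[`, "member_ids"))
  cl <- split(names(group_of), unname(part$assignments[names(group_of)]))
  for (members in cl) {
    expect_length(unique(group_of[members]), 1L)
  }
})

test_that("threaded dispatch reproduces serial partitions", {
  sim <- small_sim(seed = 23, n = 80)
  rs <- collapse_identical(suppressMessages(filter_productive(sim$rearrangements)))
  p1 <- assign_clones(rs, "recomb", "cdr3", seed = 7, threads = 1)
  p2 <- assign_clones(rs, "recomb", "cdr3", seed = 7, threads = 2)
  expect_identical(p1$assignments, p2$assignments)
})
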