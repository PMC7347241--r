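# Targeting models, mutation classification, and the T/H/M/S matrices.

test_that("targeting model constructors validate and fill motifs", {
  tm <- uniform_targeting_model(0.1)
  expect_length(tm$mutability, 1024L)
  expect_true(all(tm$mutability == 0.1))
  expect_error(uniform_targeting_model(1.3), "\\[0,1\\]")

  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("motif\tmutability", "AACGT\t0.2", "TTTTT\t0.9"), tmp)
  tm2 <- load_targeting_model(tmp)
  expect_equal(unname(tm2$mutability["AACGT"]), 0.2)
  expect_equal(unname(tm2$mutability["TTTTT"]), 0.9)
  expect_equal(sum(tm2$mutability > 0), 2L)

  writeLines(c("motif\tmutability", "AACGT\t1.3"), tmp)
  expect_error(load_targeting_model(tmp), "\\[0,1\\]")
  writeLines(c("motif\tmutability", "AACG\t0.2"), tmp)
  expect_error(load_targeting_model(tmp), "length-5")
})

test_that("hot-spot model ranks WRC/GYW above neutral above SYC/GRS", {
  tm <- hotspot_targeting_model()
  expect_gt(tm$mutability[["TACTT"]], tm$mutability[["CCACC"]])  # WRC hot
  expect_gt(tm$mutability[["CCACC"]], tm$mutability[["CCCGC"]])  # SYC cold
  expect_true(all(tm$mutability >= 0 & tm$mutability <= 1))
})

test_that("motif mutability averages IUPAC expansions and guards edges", {
  tm0 <- uniform_targeting_model(0.1)
  expect_equal(motif_mutability(tm0, "AAAAA", 3), 0.1)
  expect_equal(motif_mutability(tm0, "AAAAA", 1), 0)   # window off the edge
  expect_equal(motif_mutability(tm0, "AANAA", 3), 0)   # N in window

  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("motif\tmutability", "AACAA\t0.2", "AATAA\t0.4"), tmp)
  tm <- load_targeting_model(tmp)
  expect_equal(motif_mutability(tm, "AAYAA", 3), 0.3)
  # gaps are skipped when extracting the window
  expect_equal(motif_mutability(tm, "AA..YAA", 5), 0.3)
})

test_that("pairwise mutations classify into unique/conflicting/shared", {
  p <- classify_pair_mutations("ACCTA", "ACCTG", "ACGTA")
  expect_equal(sum(p$alpha), 1L)   # position 5: A->G in one sequence
  expect_equal(sum(p$beta), 0L)
  expect_equal(sum(p$gamma), 1L)   # position 3: G->C in both
  expect_equal(p$shared_positions, 3L)
  expect_equal(p$nu, 5)

  p2 <- classify_pair_mutations("ACGTA", "ACGTA", "ACGTA")
  expect_equal(sum(p2$alpha) + sum(p2$beta) + sum(p2$gamma), 0L)

  p3 <- classify_pair_mutations("AAGTA", "ATGTA", "ACGTA")
  expect_equal(sum(p3$beta), 1L)   # C->A vs C->T at position 2

  expect_error(classify_pair_mutations("ACG", "ACGT", "ACGT"), "length")
})

test_that("ambiguous germline codes and N bases are non-informative", {
  # egl Y at pos 2 covers C and T: neither counts as mutated
  p <- classify_pair_mutations("ACGTA", "ATGTA", "AYGTA")
  expect_equal(sum(p$alpha) + sum(p$beta) + sum(p$gamma), 0L)
  # N in a sequence removes the position from flags and from nu
  p2 <- classify_pair_mutations("NCGTA", "ACGTA", "ACGTA")
  expect_equal(p2$nu, 4.5)
  # egl N positions contribute nothing
  p3 <- classify_pair_mutations("ACGTA", "GCGTA", "NCGTA")
  expect_equal(sum(p3$alpha), 0L)
  expect_equal(p3$nu, 4)
})

test_that("mutation matrices implement the normalised counts", {
  g <- make_group(c("ACCTA", "ACCTG"), "ACGTA")
  th <- mutation_matrices(g)
  expect_equal(th$T[1, 2], 0.6)    # (1 + 2*(0+1)) / 5
  expect_equal(th$H[1, 2], 0.4)    # 2*1 / 5
  expect_true(isSymmetric(th$T))
  expect_equal(diag(th$T), c(s1 = 0, s2 = 0))

  g2 <- make_group(c("ACGTAACGTA", "GCGTAACGTC"), "ACGTAACGTA")
  th2 <- mutation_matrices(g2)
  expect_equal(th2$T[1, 2], 0.2)   # 2 unique mutations over nu = 10
  expect_equal(th2$H[1, 2], 0)

  g3 <- make_group(c("ACGTA", "ACGTA"), "ACGTA")
  th3 <- mutation_matrices(g3)
  expect_equal(th3$T[1, 2], 0)
  expect_equal(th3$H[1, 2], 0)
})

test_that("damping multiplies hot-spot survival over shared positions", {
  # no shared mutations: empty product is 1
  g0 <- make_group(c("GCGTA", "ACGTC"), "ACGTA")
  expect_equal(damping_matrix(g0, uniform_targeting_model(0.5))[1, 2], 1)

  # two shared mutations (away from the window edges) at mutability 0.1
  g2 <- make_group(c("AATAACG", "AATAACG"), "AACTACG")
  p <- classify_pair_mutations("AATAACG", "AATAACG", "AACTACG")
  expect_equal(p$shared_positions, c(3L, 4L))
  M <- damping_matrix(g2, uniform_targeting_model(0.1))
  expect_equal(M[1, 2], 0.81)

  # averaging over two germline alleles with motif mutabilities 0.2 and 0.4
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("motif\tmutability", "AACAA\t0.2", "AATAA\t0.4"), tmp)
  tm <- load_targeting_model(tmp)
  galleles <- c("AACAAAA", "AATAAAA")   # motifs at pos 3: AACAA / AATAA
  seqs <- c("AAGAAAA", "AAGAAAA")       # shared mutation at position 3
  g3 <- make_group(seqs, galleles)
  expect_equal(damping_matrix(g3, tm)[1, 2], 0.7)
})

test_that("SHM similarity follows the damped double-envelope form", {
  T <- matrix(c(0, 0.6, 0.6, 0), 2)
  H0 <- matrix(0, 2, 2)
  M1 <- matrix(1, 2, 2)
  expect_equal(shm_similarity(T, H0, M1, 0.2, 0.2)[1, 2], 0)

  H <- matrix(c(0, 0.4, 0.4, 0), 2)
  S <- shm_similarity(T, H, M1, 0.2, 0.2)
  expect_equal(S[1, 2], exp(-0.5) * (1 - exp(-2)), tolerance = 1e-12)

  # more sharing at equal totals gives higher similarity
  s_hi <- shm_similarity(T, matrix(c(0, .5, .5, 0), 2), M1, 0.2, 0.2)[1, 2]
  s_lo <- shm_similarity(T, matrix(c(0, .3, .3, 0), 2), M1, 0.2, 0.2)[1, 2]
  expect_gt(s_hi, s_lo)
  # fewer non-shared mutations at equal sharing gives higher similarity
  s_tight <- shm_similarity(matrix(c(0, .5, .5, 0), 2), H, M1, .2, .2)[1, 2]
  s_loose <- shm_similarity(matrix(c(0, .9, .9, 0), 2), H, M1, .2, .2)[1, 2]
  expect_gt(s_tight, s_loose)
})

test_that("degenerate sigmas never divide by zero", {
  T <- matrix(c(0, .4, .4, 0), 2)
  H <- matrix(c(0, .4, .4, 0), 2)
  S <- shm_similarity(T, H, matrix(1, 2, 2), 0, 0)
  expect_equal(S[1, 2], 1)       # T - H = 0 -> envelope 1; H > 0 -> term 1
  S2 <- shm_similarity(T, matrix(0, 2, 2), matrix(1, 2, 2), 0, 0)
  expect_equal(S2[1, 2], 0)
})

test_that("vectorised matrices match the brute-force oracle", {
  tm <- hotspot_targeting_model()
  withr::with_seed(101, {
    for (rep in 1:40) {
      g <- random_oracle_group(m = sample(2:8, 1), L = sample(20:60, 1))
      fast <- clonespect:::.shm_matrices(g, tm,
                                         target = "junction")
      # mask inside the group is the raw junction_mask here
      slow <- oracle_thms(g, tm)
      expect_equal(max(abs(fast$T - slow$T)), 0, tolerance = 1e-12)
      expect_equal(max(abs(fast$H - slow$H)), 0, tolerance = 1e-12)
      expect_equal(max(abs(fast$M - slow$M)), 0, tolerance = 1e-12)
      expect_equal(max(abs(fast$S - slow$S)), 0, tolerance = 1e-12)
      expect_true(all(slow$H <= slow$T + 1e-12))
    }
  })
})

test_that("a zero-mutability model disables damping entirely", {
  withr::with_seed(11, {
    g <- random_oracle_group(m = 5, L = 30)
    M <- damping_matrix(g, uniform_targeting_model(0))
    expect_true(all(M == 1))
  })
})
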