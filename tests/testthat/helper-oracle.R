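# Independent brute-force oracle for the SHM matrices: plain per-position
# loops, no shared code with the vectorised implementation.

oracle_thms <- function(group, tm, mask = group$junction_mask) {
  seqs <- group$sequences
  egl <- strsplit(group$effective_germline, "")[[1L]]
  m <- length(seqs)
  L <- length(egl)
  sets <- clonespect:::.IUPAC_SETS
  informative <- vapply(seq_len(L), function(n) {
    !(n %in% mask) && egl[n] != "N" && !(egl[n] %in% c(".", "-")) &&
      egl[n] %in% names(sets)
  }, logical(1L))
  chars <- lapply(seqs, function(s) strsplit(s, "")[[1L]])
  acgt <- c("A", "C", "G", "T")

  Tm <- matrix(0, m, m); Hm <- matrix(0, m, m); Mm <- matrix(1, m, m)
  for (i in seq_len(m - 1L)) for (j in seq.int(i + 1L, m)) {
    a <- 0L; b <- 0L; g <- 0L
    shared_pos <- integer(0)
    for (n in which(informative)) {
      ci <- chars[[i]][n]; cj <- chars[[j]][n]
      if (!(ci %in% acgt) || !(cj %in% acgt)) next
      mi <- !(ci %in% sets[[egl[n]]])
      mj <- !(cj %in% sets[[egl[n]]])
      if (mi && mj && ci == cj) { g <- g + 1L; shared_pos <- c(shared_pos, n) }
      else if (mi && mj) b <- b + 1L
      else if (xor(mi, mj)) a <- a + 1L
    }
    ni <- sum(vapply(which(informative), function(n)
      chars[[i]][n] %in% acgt, logical(1L)))
    nj <- sum(vapply(which(informative), function(n)
      chars[[j]][n] %in% acgt, logical(1L)))
    nu <- (ni + nj) / 2
    if (nu > 0) {
      Tm[i, j] <- Tm[j, i] <- (a + 2 * (b + g)) / nu
      Hm[i, j] <- Hm[j, i] <- 2 * g / nu
    }
    prod_m <- 1
    for (n in shared_pos) {
      mus <- vapply(group$germlines, function(gl)
        motif_mutability(tm, gl, n), numeric(1L))
      prod_m <- prod_m * (1 - mean(mus))
    }
    Mm[i, j] <- Mm[j, i] <- prod_m
  }
  pop_sd <- function(x) { v <- x[upper.tri(x)]; sqrt(mean((v - mean(v))^2)) }
  sT <- pop_sd(Tm); sH <- pop_sd(Hm)
  gauss <- function(x, s) if (s > 0) exp(-x^2 / (2 * s^2)) else (x == 0) * 1
  Sm <- Mm * gauss(Tm - Hm, sT) * (1 - gauss(Hm, sH))
  Sm[Hm == 0] <- 0
  diag(Sm) <- 0
  list(T = Tm, H = Hm, M = Mm, S = Sm)
}

# random group of short sequences for oracle comparisons
random_oracle_group <- function(m = 5L, L = 40L) {
  gl1 <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  germs <- gl1
  if (stats::runif(1L) < 0.3) {   # occasionally two alleles
    ch <- strsplit(gl1, "")[[1L]]
    p <- sample.int(L, 1L)
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
    germs <- c(gl1, paste(ch, collapse = ""))
  }
  seqs <- vapply(seq_len(m), function(i) {
    ch <- strsplit(sample(germs, 1L), "")[[1L]]
    nmut <- stats::rpois(1L, 3)
    for (p in sample.int(L, min(nmut, L))) {
      ch[p] <- sample(c("A", "C", "G", "T", "N"), 1L,
                      prob = c(rep(0.24, 4), 0.04))
    }
    paste(ch, collapse = "")
  }, "")
  mask <- if (stats::runif(1L) < 0.5) integer(0) else seq_len(6L)
  make_group(seqs, germs, junction_mask = mask)
}
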