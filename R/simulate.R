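# Ground-truth repertoire simulator. Clones are founded by random V(D)J
# recombination from a germline pool (the D segment is folded into the
# random junction insert), expanded along a stochastically branching binary
# lineage tree, and mutated by 5-mer context-dependent point substitutions.
# The branch from the germline to the most recent common ancestor is drawn
# like any other branch, which is what creates clone-wide shared mutations.

#' Simulation parameters
#'
#' Defaults describe a desk-scale repertoire: ~2000 sequences with
#' gamma-distributed clone sizes (shape 0.75, scale 0.75, amplitude ~ Normal
#' (20, 2), plus 1), junction lengths 33-48 nt, and lineage-tree somatic
#' hypermutation producing mutation loads around 2-10% of sites. The
#' mutation rate is calibrated so that roughly 95% of non-singleton clones
#' carry at least one pairwise shared V/J mutation, the regime in which
#' shared-mutation information is informative but not saturating.
#'
#' @param n_sequences_mean,n_sequences_sd total repertoire size ~ Normal.
#' @param clone_size_gamma_shape,clone_size_gamma_scale gamma law of clone
#'   sizes.
#' @param clone_size_amplitude_mean,clone_size_amplitude_sd per-clone
#'   amplitude ~ Normal; clone size = round(amplitude * gamma) + 1.
#' @param mutation_rate_per_branch expected substitutions per site on an
#'   average internal lineage-tree branch. Branch lengths vary around this
#'   mean (Gamma(3, 1/3) length factors: cells divide and are sampled at
#'   irregular intervals).
#' @param pendant_branch_factor mean length multiplier for terminal
#'   (pendant) branches. Observed B cell lineage trees carry long terminal
#'   branches (mutations unique to each sampled sequence).
#' @param clone_maturity_shape,clone_maturity_scale gamma law of the
#'   per-clone maturity factor multiplying all branch lengths: repertoires
#'   mix barely-mutated recent clones with heavily mutated ones, which
#'   spreads per-sequence mutation loads the way real repertoires spread
#'   them.
#' @param branching_prob probability that a branching event splits a
#'   uniformly chosen leaf (balanced, Yule-like growth); otherwise the most
#'   recently created leaf splits (caterpillar tendency).
#' @param germline_pool list with character vectors `v`, `d` (optional) and
#'   `j` of named germline templates (default [toy_germline_pool()]).
#' @param junction_length_range inclusive junction length range in nt;
#'   lengths are drawn uniformly among multiples of 3.
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_sequences_mean = 2000, n_sequences_sd = 200,
                       clone_size_gamma_shape = 0.75,
                       clone_size_gamma_scale = 0.75,
                       clone_size_amplitude_mean = 20,
                       clone_size_amplitude_sd = 2,
                       mutation_rate_per_branch = 0.0055,
                       pendant_branch_factor = 4,
                       clone_maturity_shape = 2,
                       clone_maturity_scale = 0.5,
                       branching_prob = 0.9,
                       germline_pool = toy_germline_pool(),
                       junction_length_range = c(33L, 48L)) {
  stopifnot(n_sequences_mean > 0, n_sequences_sd >= 0,
            clone_size_gamma_shape > 0, clone_size_gamma_scale > 0,
            clone_size_amplitude_mean > 0,
            mutation_rate_per_branch >= 0, pendant_branch_factor >= 1,
            clone_maturity_shape > 0, clone_maturity_scale > 0,
            branching_prob > 0, branching_prob <= 1,
            length(germline_pool$v) > 0, length(germline_pool$j) > 0,
            junction_length_range[1L] >= 9L,
            junction_length_range[2L] >= junction_length_range[1L])
  structure(list(
    n_sequences_mean = n_sequences_mean, n_sequences_sd = n_sequences_sd,
    clone_size_gamma_shape = clone_size_gamma_shape,
    clone_size_gamma_scale = clone_size_gamma_scale,
    clone_size_amplitude_mean = clone_size_amplitude_mean,
    clone_size_amplitude_sd = clone_size_amplitude_sd,
    mutation_rate_per_branch = mutation_rate_per_branch,
    pendant_branch_factor = pendant_branch_factor,
    clone_maturity_shape = clone_maturity_shape,
    clone_maturity_scale = clone_maturity_scale,
    branching_prob = branching_prob,
    germline_pool = germline_pool,
    junction_length_range = junction_length_range
  ), class = "sim_params")
}

.NONSTOP_CODONS <- local({
  b <- c("A", "C", "G", "T")
  all3 <- apply(expand.grid(b, b, b, stringsAsFactors = FALSE), 1L,
                paste, collapse = "")
  setdiff(all3, .STOP_CODONS)
})

.random_codons <- function(n) {
  paste(sample(.NONSTOP_CODONS, n, replace = TRUE), collapse = "")
}

#' Built-in toy germline pool
#'
#' A deterministic synthetic pool of 12 V templates (300 nt, ending in the
#' conserved TGT cysteine codon), 6 D templates (21-30 nt), and 4 J
#' templates (48 nt, starting with the conserved TGG tryptophan codon),
#' generated from non-stop codons so that unmutated rearrangements are
#' in-frame and productive. Shared D templates make junctions from
#' independent clones partially similar, as in real repertoires. These are
#' synthetic stand-ins with realistic lengths and conserved junction
#' flanks, not IMGT sequences; a real germline FASTA can be supplied via
#' [read_germline_pool()].
#'
#' @return List with named character vectors `v`, `d` and `j`.
#' @export
toy_germline_pool <- function() {
  withr::with_seed(20200623, {
    v <- vapply(seq_len(12L), function(i) paste0(.random_codons(99L), "TGT"), "")
    j <- vapply(seq_len(4L), function(i) paste0("TGG", .random_codons(15L)), "")
    dlen <- c(21L, 24L, 27L, 30L, 24L, 27L)
    d <- vapply(dlen, function(n) .random_codons(n %/% 3L), "")
  })
  list(v = stats::setNames(v, sprintf("IGHV1-S%d*01", seq_along(v))),
       d = stats::setNames(d, sprintf("IGHD1-S%d*01", seq_along(d))),
       j = stats::setNames(j, sprintf("IGHJ%d*01", seq_along(j))))
}

#' Read a germline pool from FASTA
#'
#' V, D and J templates are recognised by `IGHV`/`IGHD`/`IGHJ` (or the
#' light-chain equivalents) in the record names; D templates are optional.
#'
#' @param path FASTA file of germline templates.
#' @return List with named character vectors `v`, `d` and `j`.
#' @export
read_germline_pool <- function(path) {
  fa <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE)
  seqs <- toupper(vapply(fa, as.character, ""))
  names(seqs) <- names(fa)
  v <- seqs[grepl("^IG.V", names(seqs))]
  d <- seqs[grepl("^IG.D", names(seqs))]
  j <- seqs[grepl("^IG.J", names(seqs))]
  if (length(v) == 0L || length(j) == 0L) {
    stop("germline FASTA must contain IG.V and IG.J records", call. = FALSE)
  }
  list(v = v, d = d, j = j)
}

#' Sample one V(D)J recombination event
#'
#' Picks V, D and J templates uniformly at random and draws a junction
#' length uniformly among multiples of 3 within the configured range. The
#' insert between V and J is built as N-nucleotides + (possibly trimmed) D
#' segment + N-nucleotides, so that independent clones sharing a D template
#' have partially similar junctions, as in real repertoires. Founders whose
#' random N regions create an in-frame stop codon are redrawn
#' (nonproductive rearrangements are never observed). The junction covers
#' the last codon of V through the first codon of J. Uses the current RNG
#' stream.
#'
#' @param params a `sim_params`.
#' @return List describing the unmutated founder: `sequence`, `v_call`,
#'   `j_call`, `junction`, `junction_start`, `junction_length`.
#' @export
sample_recombination <- function(params) {
  pool <- params$germline_pool
  if (length(pool$v) == 0L || length(pool$j) == 0L) {
    stop("empty germline pool", call. = FALSE)
  }
  lens <- seq.int(params$junction_length_range[1L],
                  params$junction_length_range[2L])
  lens <- lens[lens %% 3L == 0L]
  for (try in seq_len(50L)) {
    vi <- sample.int(length(pool$v), 1L)
    ji <- sample.int(length(pool$j), 1L)
    v <- unname(pool$v[vi]); j <- unname(pool$j[ji])
    jl <- if (length(lens) == 1L) lens else sample(lens, 1L)
    insert_len <- jl - 6L
    if (length(pool$d) > 0L) {
      d <- unname(pool$d[sample.int(length(pool$d), 1L)])
      keep <- min(nchar(d), insert_len)
      off <- sample.int(nchar(d) - keep + 1L, 1L) - 1L
      d_use <- substr(d, off + 1L, off + keep)
      n_total <- insert_len - keep
    } else {
      d_use <- ""
      n_total <- insert_len
    }
    n1 <- if (n_total > 0L) sample.int(n_total + 1L, 1L) - 1L else 0L
    n2 <- n_total - n1
    rand_nt <- function(n) if (n > 0L) {
      paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    } else ""
    insert <- paste0(rand_nt(n1), d_use, rand_nt(n2))
    seq <- paste0(v, insert, j)
    if (!.has_stop_codon(seq)) break
  }
  junction_start <- nchar(v) - 2L
  list(sequence = seq,
       v_call = names(pool$v)[vi],
       j_call = names(pool$j)[ji],
       junction = substr(seq, junction_start, junction_start + jl - 1L),
       junction_start = junction_start,
       junction_length = jl)
}

# One branch of SHM: Poisson(rate * length_factor * L) substitutions at
# positions drawn without replacement proportionally to the 5-mer mutability
# of the current sequence (uniform when the model is flat zero). Substituted
# bases are drawn uniformly among the three alternatives, but a substitution
# that would create an in-frame stop codon is redirected to a non-stop
# alternative (or skipped): B cells whose receptor acquires a nonsense
# mutation are lost to selection and never observed.
.mutate_branch <- function(sequence, params, tm, length_factor = 1) {
  L <- nchar(sequence)
  n <- stats::rpois(1L, params$mutation_rate_per_branch * length_factor * L)
  n <- min(n, L)
  if (n == 0L) return(list(sequence = sequence, positions = integer(0)))
  wts <- .position_mutability(tm, sequence, L)
  if (sum(wts) <= 0) wts <- rep(1, L)
  pos <- sample.int(L, n, prob = wts)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  mutated <- integer(0)
  for (p in pos) {
    codon_start <- 3L * ((p - 1L) %/% 3L) + 1L
    alts <- sample(setdiff(c("A", "C", "G", "T"), chars[p]))
    for (b in alts) {
      codon <- chars[codon_start:min(codon_start + 2L, L)]
      codon[p - codon_start + 1L] <- b
      if (length(codon) < 3L || !(paste(codon, collapse = "") %in%
                                  .STOP_CODONS)) {
        chars[p] <- b
        mutated <- c(mutated, p)
        break
      }
    }
  }
  list(sequence = paste(chars, collapse = ""), positions = mutated)
}

#' Expand a founder into a clone along a random lineage tree
#'
#' Grows a bifurcating tree topology to `size` leaves, then introduces
#' mutations along every edge from the root down, so leaves inherit all
#' ancestral substitutions. The root branch (germline to most recent common
#' ancestor) is mutated like any internal branch; its substitutions are
#' shared by every member and are what makes clone members share mutations.
#' Terminal (pendant) branches are `pendant_branch_factor` times longer,
#' reproducing the long terminal branches of observed B cell lineages. At
#' each branching event either a uniformly chosen leaf splits (probability
#' `branching_prob`) or the most recently created one. No indels are
#' introduced; the junction length is preserved.
#'
#' @param founder a founder from [sample_recombination()].
#' @param size number of observed sequences (leaves), >= 1.
#' @param params a `sim_params`.
#' @param tm `targeting_model` driving mutation placement (default: built-in
#'   synthetic hot-spot model).
#' @return List with character vector `sequences` (length `size`),
#'   `root_mutations` (count on the root branch), and `n_branches`.
#' @export
evolve_clone <- function(founder, size, params,
                         tm = hotspot_targeting_model()) {
  stopifnot(size >= 1L)
  # phase 1: topology (parent pointers; node 1 is the MRCA)
  parent <- c(0L)
  is_leaf <- c(TRUE)
  leaves <- 1L
  while (length(leaves) < size) {
    pick <- if (stats::runif(1L) < params$branching_prob) {
      sample.int(length(leaves), 1L)
    } else {
      length(leaves)
    }
    node <- leaves[pick]
    id1 <- length(parent) + 1L; id2 <- length(parent) + 2L
    parent <- c(parent, node, node)
    is_leaf[node] <- FALSE
    is_leaf[c(id1, id2)] <- TRUE
    leaves <- c(leaves[-pick], id1, id2)
  }
  # phase 2: mutations along edges, root-down (parents precede children).
  # Edge lengths are Gamma(3, 1/3)-distributed multiples (mean 1, moderate
  # spread) of the mean branch length; pendant edges get the pendant factor
  # on top. A singleton clone is root branch plus one pendant branch.
  n_nodes <- length(parent)
  seqs <- character(n_nodes)
  redge <- function() stats::rgamma(1L, shape = 3, scale = 1 / 3)
  root_fac <- redge() +
    if (size == 1L) params$pendant_branch_factor * redge() else 0
  root <- .mutate_branch(founder$sequence, params, tm,
                         length_factor = root_fac)
  seqs[1L] <- root$sequence
  if (n_nodes > 1L) {
    for (node in 2L:n_nodes) {
      fac <- redge() *
        (if (is_leaf[node]) params$pendant_branch_factor else 1)
      seqs[node] <- .mutate_branch(seqs[parent[node]], params, tm,
                                   length_factor = fac)$sequence
    }
  }
  list(sequences = seqs[is_leaf],
       root_mutations = length(root$positions),
       n_branches = n_nodes)
}

#' Simulate a ground-truth-labelled repertoire
#'
#' Draws the total repertoire size from a normal law, then founds clones one
#' by one (random V(D)J recombination; clone size `round(amplitude * gamma) +
#' 1`) until the total is reached, evolving each clone along its own lineage
#' tree. Deterministic given `seed`.
#'
#' @param params a `sim_params`.
#' @param seed integer seed.
#' @param tm `targeting_model` for mutation placement (default: built-in
#'   synthetic hot-spot model).
#' @return List with `rearrangements` (a `rearrangement_set` including a
#'   truth `clone_id` column), `truth` (data.frame `sequence_id`,
#'   `clone_id`), and `clones` (per-clone metadata: size, root-branch
#'   mutation count, gene calls, junction length).
#' @export
simulate_repertoire <- function(params = sim_params(), seed = 1L,
                                tm = hotspot_targeting_model()) {
  withr::with_seed(as.integer(seed), {
    total <- max(1L, round(stats::rnorm(1L, params$n_sequences_mean,
                                        params$n_sequences_sd)))
    rows <- list()
    meta <- list()
    emitted <- 0L
    clone_idx <- 0L
    while (emitted < total) {
      clone_idx <- clone_idx + 1L
      amplitude <- max(1, stats::rnorm(1L, params$clone_size_amplitude_mean,
                                       params$clone_size_amplitude_sd))
      g <- stats::rgamma(1L, shape = params$clone_size_gamma_shape,
                         scale = params$clone_size_gamma_scale)
      size <- as.integer(round(amplitude * g)) + 1L
      founder <- sample_recombination(params)
      maturity <- stats::rgamma(1L, shape = params$clone_maturity_shape,
                                scale = params$clone_maturity_scale)
      cparams <- params
      cparams$mutation_rate_per_branch <-
        params$mutation_rate_per_branch * maturity
      clone <- evolve_clone(founder, size, cparams, tm)
      cid <- sprintf("C%04d", clone_idx)
      jl <- founder$junction_length
      js <- founder$junction_start
      rows[[clone_idx]] <- data.frame(
        sequence_id = sprintf("%s.%03d", cid, seq_len(size)),
        sequence_alignment = clone$sequences,
        germline_alignment = founder$sequence,
        v_call = founder$v_call,
        j_call = founder$j_call,
        junction = substr(clone$sequences, js, js + jl - 1L),
        junction_length = jl,
        productive = TRUE,
        duplicate_count = 1L,
        clone_id = cid,
        stringsAsFactors = FALSE)
      meta[[clone_idx]] <- data.frame(
        clone_id = cid, size = size, maturity = maturity,
        root_mutations = clone$root_mutations,
        n_branches = clone$n_branches,
        v_call = founder$v_call, j_call = founder$j_call,
        junction_length = jl, stringsAsFactors = FALSE)
      emitted <- emitted + size
    }
    df <- do.call(rbind, rows)
    rownames(df) <- NULL
    rs <- .new_rearrangement_set(df, provenance = list(
      path = sprintf("simulated(seed=%d)", as.integer(seed)),
      dialect = "airr", filters = character(0)))
    list(rearrangements = rs,
         truth = df[, c("sequence_id", "clone_id")],
         clones = do.call(rbind, meta))
  })
}
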