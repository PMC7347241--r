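# Partition unique sequences into VJ(l)-groups — sequences sharing IGHV
# gene, IGHJ gene and junction length — and build each group's effective
# IUPAC germline. Groups are the independent substrate for clustering.

#' Parse a V or J gene call into a set of gene names
#'
#' Splits comma-separated multiple assignments, strips allele suffixes
#' (`*NN`), and removes duplicates, so `"IGHV1-2*02,IGHV1-2*04"` becomes the
#' single gene `"IGHV1-2"`.
#'
#' @param call a gene call string.
#' @return Character vector of unique gene names.
#' @export
parse_gene_calls <- function(call) {
  if (length(call) != 1L || is.na(call) || !nzchar(call)) {
    stop("empty gene call", call. = FALSE)
  }
  genes <- trimws(strsplit(call, ",", fixed = TRUE)[[1L]])
  genes <- sub("\\*.*$", "", genes)
  genes <- unique(genes[nzchar(genes)])
  if (length(genes) == 0L) stop("empty gene call", call. = FALSE)
  genes
}

.gene_sets <- function(calls) lapply(calls, parse_gene_calls)

#' Effective IUPAC germline of a set of aligned germlines
#'
#' Per alignment position, returns the minimal IUPAC code whose nucleotide
#' set equals the union of the bases observed across all input germlines
#' (allele-grouping). Positions where every input is a gap stay gaps;
#' positions mixing gaps and bases take the union of the bases; `N` in any
#' input forces `N`.
#'
#' @param germlines character vector of equal-length aligned germlines.
#' @return A single IUPAC string of the common alignment length.
#' @examples
#' effective_germline(c("ACGT", "ATGT"))  # "AYGT"
#' @export
effective_germline <- function(germlines) {
  if (length(germlines) == 0L) stop("need at least one germline", call. = FALSE)
  mat <- .char_matrix(germlines)
  out <- character(ncol(mat))
  for (p in seq_len(ncol(mat))) {
    col <- mat[, p]
    bases <- col[!.is_gap(col)]
    if (length(bases) == 0L) {   # all gaps: keep the first gap character
      out[p] <- col[1L]
      next
    }
    sets <- .IUPAC_SETS[bases]
    if (any(vapply(sets, is.null, logical(1L)))) {
      out[p] <- "N"              # unknown character: non-informative
      next
    }
    u <- sort(unique(unlist(sets, use.names = FALSE)))
    out[p] <- .IUPAC_FROM_SET[[paste(u, collapse = "")]]
  }
  paste(out, collapse = "")
}

# Alignment-coordinate positions covered by the junction of one record.
.junction_span <- function(sequence_alignment, junction) {
  ungapped <- .strip_gaps(sequence_alignment)
  start <- regexpr(junction, ungapped, fixed = TRUE)[[1L]]
  if (start < 1L) return(integer(0))
  map <- .ungapped_map(sequence_alignment)
  map[seq.int(start, start + nchar(junction) - 1L)]
}

.new_vjl_group <- function(group_id, idx, rs) {
  # canonical member order: groups must not depend on input row order
  idx <- idx[order(rs$sequence_id[idx])]
  members <- rs[idx, , drop = FALSE]
  vsets <- .gene_sets(members$v_call)
  jsets <- .gene_sets(members$j_call)
  germs <- unique(members$germline_alignment)
  mask <- sort(unique(unlist(mapply(.junction_span,
                                    members$sequence_alignment,
                                    members$junction,
                                    SIMPLIFY = FALSE),
                             use.names = FALSE)))
  structure(list(
    group_id = group_id,
    member_ids = members$sequence_id,
    v_genes = sort(unique(unlist(vsets, use.names = FALSE))),
    j_genes = sort(unique(unlist(jsets, use.names = FALSE))),
    junction_length = members$junction_length[1L],
    sequences = members$sequence_alignment,
    junctions = members$junction,
    germlines = germs,
    effective_germline = effective_germline(germs),
    junction_mask = mask
  ), class = "vjl_group")
}

#' @export
print.vjl_group <- function(x, ...) {
  cat(sprintf("VJ(l)-group %s: %d sequence(s), V={%s}, J={%s}, l=%d\n",
              x$group_id, length(x$member_ids),
              paste(x$v_genes, collapse = ","),
              paste(x$j_genes, collapse = ","),
              x$junction_length))
  invisible(x)
}

# union-find over integer indices
.uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

#' Build VJ(l)-groups
#'
#' Partitions a (collapsed) rearrangement set into groups that share IGHV
#' gene, IGHJ gene and junction length. In `exact` mode, the key is the
#' sorted V-gene set, sorted J-gene set and junction length. In `chain` mode
#' (default, matching how ambiguous multi-gene assignments are handled),
#' sequences with intersecting V-gene sets *and* intersecting J-gene sets are
#' connected, and groups are the connected components (transitive closure)
#' within each junction length. Junction length is always a hard key, since
#' clone members are assumed to evolve by point mutation only.
#'
#' @param rs a collapsed `rearrangement_set`.
#' @param mode `"chain"` (default) or `"exact"`.
#' @return A list of `vjl_group` objects covering every sequence exactly once.
#' @export
build_vjl_groups <- function(rs, mode = c("chain", "exact")) {
  mode <- match.arg(mode)
  n <- nrow(rs)
  if (n == 0L) return(list())
  vsets <- .gene_sets(rs$v_call)
  jsets <- .gene_sets(rs$j_call)
  vkey <- vapply(vsets, function(s) paste(sort(s), collapse = ","), "")
  jkey <- vapply(jsets, function(s) paste(sort(s), collapse = ","), "")
  exact_key <- paste(vkey, jkey, rs$junction_length, sep = "|")

  if (mode == "exact") {
    comp_of_seq <- match(exact_key, unique(exact_key))
  } else {
    # chain: union-find over the distinct exact keys within each length
    ukeys <- unique(exact_key)
    uidx <- match(ukeys, exact_key)        # one exemplar row per key
    parent <- seq_along(ukeys)
    lens <- rs$junction_length[uidx]
    for (len in unique(lens)) {
      ks <- which(lens == len)
      if (length(ks) < 2L) next
      for (a in seq_along(ks)[-length(ks)]) {
        for (b in seq.int(a + 1L, length(ks))) {
          i <- ks[a]; j <- ks[b]
          if (length(intersect(vsets[[uidx[i]]], vsets[[uidx[j]]])) > 0L &&
              length(intersect(jsets[[uidx[i]]], jsets[[uidx[j]]])) > 0L) {
            ri <- .uf_find(parent, i); rj <- .uf_find(parent, j)
            if (ri != rj) parent[min(ri, rj)] <- parent[max(ri, rj)] <- min(ri, rj)
          }
        }
      }
    }
    roots <- vapply(seq_along(ukeys), function(i) .uf_find(parent, i), 0L)
    comp_of_key <- match(roots, unique(roots))
    comp_of_seq <- comp_of_key[match(exact_key, ukeys)]
  }

  # deterministic group numbering: order components by content, not by the
  # order rows happened to arrive in
  comps <- split(seq_len(n), comp_of_seq)
  comp_key <- vapply(comps, function(idx)
    min(rs$sequence_id[idx]), "")
  comps <- comps[order(comp_key)]
  groups <- vector("list", length(comps))
  for (g in seq_along(comps)) {
    idx <- comps[[g]]
    gid <- sprintf("%s_%s_%d_%d",
                   paste(sort(unique(unlist(vsets[idx]))), collapse = "-"),
                   paste(sort(unique(unlist(jsets[idx]))), collapse = "-"),
                   rs$junction_length[idx[1L]], g)
    groups[[g]] <- .new_vjl_group(gid, idx, rs)
  }
  groups
}
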