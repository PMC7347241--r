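# Shared-mutation prevalence across true clones: the fraction of
# non-singleton clones in which at least one sequence pair shares a somatic
# hypermutation at the same V/J-segment position.

#' Shared-SHM prevalence across clones
#'
#' For every clone with at least two members, builds the pairwise
#' shared-mutation matrix `H` over the V and J segments (junction excluded)
#' against the clone's germline and reports whether any sequence pair shares
#' a mutation. Clonally related cells inherit the mutations of their common
#' ancestors, so most non-singleton clones are expected to contain shared
#' mutations; the few without tend to be small clones whose common ancestor
#' branch carried none.
#'
#' @param rs a `rearrangement_set` (e.g. simulator output).
#' @param truth named vector or data.frame (`sequence_id`, `clone_id`)
#'   giving the true clone of every sequence.
#' @return List with `prevalence` (fraction of non-singleton clones with any
#'   shared pair) and `per_clone` data.frame (`clone_id`, `size`,
#'   `mean_H`, `any_shared`).
#' @export
shared_shm_prevalence <- function(rs, truth) {
  if (is.data.frame(truth)) {
    truth <- stats::setNames(truth$clone_id, truth$sequence_id)
  }
  labels <- truth[rs$sequence_id]
  out <- list()
  for (cid in unique(labels)) {
    idx <- which(labels == cid)
    if (length(idx) < 2L) next
    group <- .new_vjl_group(cid, idx, rs)
    H <- mutation_matrices(group, target = "junction")$H
    hv <- H[upper.tri(H)]
    out[[length(out) + 1L]] <- data.frame(
      clone_id = cid, size = length(idx), mean_H = mean(hv),
      any_shared = any(hv > 0), stringsAsFactors = FALSE)
  }
  per_clone <- if (length(out) > 0L) do.call(rbind, out) else
    data.frame(clone_id = character(0), size = integer(0),
               mean_H = numeric(0), any_shared = logical(0))
  list(prevalence = mean(per_clone$any_shared), per_clone = per_clone)
}
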