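# Evaluation of inferred clone partitions: pairwise confusion counts against
# ground truth, shared-mutation enrichment against size-matched negative
# controls, and the cross-individual spike-in specificity protocol.

#' Pairwise confusion counts between two labelings
#'
#' Classifies every unordered sequence pair by whether it is clonally
#' related in the truth and in the prediction: TP (related, predicted
#' related), FN (related, predicted unrelated), FP (unrelated, predicted
#' related), TN (unrelated, predicted unrelated). Computed via contingency
#' table pair counts, so it scales to large repertoires.
#'
#' @param truth,predicted named vectors (`sequence_id -> clone label`) over
#'   the same id set, or unnamed vectors in the same order.
#' @return List with integer-valued `TP`, `FP`, `TN`, `FN` summing to
#'   `choose(m, 2)`.
#' @export
pairwise_confusion <- function(truth, predicted) {
  if (!is.null(names(truth)) && !is.null(names(predicted))) {
    if (!setequal(names(truth), names(predicted))) {
      stop("truth and predicted labelings cover different sequence ids",
           call. = FALSE)
    }
    predicted <- predicted[names(truth)]
  } else if (length(truth) != length(predicted)) {
    stop("labelings have different lengths", call. = FALSE)
  }
  m <- length(truth)
  pairs <- function(n) sum(n * (n - 1) / 2)
  joint <- table(truth, predicted)
  TP <- pairs(as.numeric(joint))
  truth_pairs <- pairs(as.numeric(table(truth)))
  pred_pairs <- pairs(as.numeric(table(predicted)))
  FN <- truth_pairs - TP
  FP <- pred_pairs - TP
  TN <- m * (m - 1) / 2 - TP - FN - FP
  list(TP = TP, FP = FP, TN = TN, FN = FN)
}

#' Sensitivity, specificity and precision from confusion counts
#'
#' Sensitivity = TP/(TP+FN) (fraction of truly clonal pairs recovered),
#' specificity = TN/(TN+FP) (fraction of unrelated pairs kept apart),
#' precision = TP/(TP+FP). A zero denominator yields `NA` (undefined),
#' which callers exclude from averages.
#'
#' @param cc confusion counts from [pairwise_confusion()].
#' @return Named numeric vector `sensitivity`, `specificity`, `precision`.
#' @export
confusion_metrics <- function(cc) {
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  c(sensitivity = ratio(cc$TP, cc$TP + cc$FN),
    specificity = ratio(cc$TN, cc$TN + cc$FP),
    precision = ratio(cc$TP, cc$TP + cc$FP))
}

#' Shared-mutation enrichment against negative controls
#'
#' For each true clone (>= 2 members) found in the largest VJ(l)-groups,
#' compares the observed mean pairwise shared-mutation value (mean of the
#' upper-triangular `H` entries over the clone members) with a null
#' distribution built from size-matched artificial clones sampled uniformly
#' without replacement from the same VJ(l)-group (excluding the clone's own
#' exact member set). The empirical p-value is the fraction of controls
#' whose mean `H` is at least the observed value.
#'
#' @param rs a filtered, collapsed `rearrangement_set`.
#' @param truth named vector `sequence_id -> true clone id`.
#' @param n_controls number of negative controls per clone (the full
#'   protocol uses 1000; default 100).
#' @param n_top_groups number of largest VJ(l)-groups scanned (the full
#'   protocol uses 100; default 20).
#' @param seed integer seed for control sampling.
#' @param target `"junction"` or `"cdr3"` SHM span.
#' @return data.frame with one row per evaluated clone: `clone_id`,
#'   `group_id`, `size`, `observed_H`, `control_mean_H`, `p_value`.
#' @export
negative_control_enrichment <- function(rs, truth, n_controls = 100L,
                                        n_top_groups = 20L, seed = 1L,
                                        target = c("junction", "cdr3")) {
  target <- match.arg(target)
  groups <- build_vjl_groups(rs)
  sizes <- vapply(groups, function(g) length(g$member_ids), 0L)
  groups <- groups[order(sizes, decreasing = TRUE)]
  groups <- groups[seq_len(min(n_top_groups, length(groups)))]
  out <- list()
  withr::with_seed(as.integer(seed), {
    for (group in groups) {
      m <- length(group$member_ids)
      if (m < 2L) next
      H <- mutation_matrices(group, target)$H
      labels <- truth[group$member_ids]
      for (cid in unique(labels)) {
        members <- which(labels == cid)
        s <- length(members)
        if (s < 2L) next
        obs <- mean(H[members, members][upper.tri(diag(s))])
        if (s >= m) next    # cannot sample a different set of the same size
        ctrl <- numeric(n_controls)
        for (b in seq_len(n_controls)) {
          repeat {
            pick <- sample.int(m, s)
            if (!setequal(pick, members)) break
          }
          ctrl[b] <- mean(H[pick, pick][upper.tri(diag(s))])
        }
        out[[length(out) + 1L]] <- data.frame(
          clone_id = cid, group_id = group$group_id, size = s,
          observed_H = obs, control_mean_H = mean(ctrl),
          p_value = mean(ctrl >= obs), stringsAsFactors = FALSE)
      }
    }
  })
  if (length(out) == 0L) {
    return(data.frame(clone_id = character(0), group_id = character(0),
                      size = integer(0), observed_H = numeric(0),
                      control_mean_H = numeric(0), p_value = numeric(0)))
  }
  do.call(rbind, out)
}

#' Cross-individual spike-in specificity
#'
#' Specificity protocol for data without ground truth: one repertoire is the
#' "base"; in each cycle one random sequence from every other repertoire is
#' spiked into the base and clones are assigned. Spiked sequences that end
#' up as singletons are true negatives (clones cannot span individuals);
#' spiked sequences grouped into larger clones are false positives.
#'
#' @param repertoires list of `rearrangement_set` objects (>= 2).
#' @param base_index index of the base repertoire.
#' @param cycles number of spike-in cycles.
#' @param seed integer seed.
#' @param method,target,tm clustering configuration, as in [assign_clones()].
#' @return List with `specificity` (mean over cycles) and `per_cycle`
#'   data.frame (`cycle`, `TN`, `FP`).
#' @export
cross_individual_specificity <- function(repertoires, base_index = 1L,
                                         cycles = 10L, seed = 1L,
                                         method = "integrated",
                                         target = "cdr3", tm = NULL) {
  if (length(repertoires) < 2L) {
    stop("need at least 2 repertoires", call. = FALSE)
  }
  base <- repertoires[[base_index]]
  if (nrow(base) < 2L) stop("base repertoire needs >= 2 sequences",
                            call. = FALSE)
  others <- repertoires[-base_index]
  per_cycle <- data.frame(cycle = integer(0), TN = integer(0), FP = integer(0))
  cycle_seeds <- withr::with_seed(as.integer(seed),
                                  sample.int(2147483646L, cycles))
  for (cy in seq_len(cycles)) {
    spiked <- withr::with_seed(cycle_seeds[cy], {
      lapply(seq_along(others), function(oi) {
        row <- others[[oi]][sample.int(nrow(others[[oi]]), 1L), , drop = FALSE]
        row$sequence_id <- sprintf("spike%d_cycle%d_%s", oi, cy,
                                   row$sequence_id)
        row
      })
    })
    common <- Reduce(intersect, c(list(names(base)),
                                  lapply(spiked, names)))
    combined <- rbind(as.data.frame(base)[, common, drop = FALSE],
                      do.call(rbind, lapply(spiked, function(x) {
                        as.data.frame(x)[, common, drop = FALSE]
                      })))
    crs <- .new_rearrangement_set(combined)
    crs <- collapse_identical(crs)
    part <- assign_clones(crs, method = method, target = target, tm = tm,
                          seed = cycle_seeds[cy])
    spike_ids <- unlist(lapply(spiked, `[[`, "sequence_id"))
    clone_sizes <- table(part$assignments)
    spike_clones <- part$assignments[spike_ids]
    tn <- sum(clone_sizes[spike_clones] == 1L)
    fp <- length(spike_ids) - tn
    per_cycle <- rbind(per_cycle, data.frame(cycle = cy, TN = tn, FP = fp))
  }
  list(specificity = mean(per_cycle$TN / (per_cycle$TN + per_cycle$FP)),
       per_cycle = per_cycle)
}
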