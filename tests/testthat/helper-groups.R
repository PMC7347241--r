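# Build small in-memory fixtures without touching disk.

# A minimal vjl_group from raw aligned sequences. junction_mask defaults to
# empty so the whole alignment is analysed; pass junctions/junction_mask to
# exercise masking.
make_group <- function(seqs, germlines, junctions = NULL,
                       junction_mask = integer(0), ids = NULL) {
  ids <- ids %||% sprintf("s%d", seq_along(seqs))
  junctions <- junctions %||% seqs
  structure(list(
    group_id = "G1",
    member_ids = ids,
    v_genes = "IGHV1-T", j_genes = "IGHJ1",
    junction_length = nchar(junctions[1L]),
    sequences = seqs,
    junctions = junctions,
    germlines = unique(germlines),
    effective_germline = effective_germline(germlines),
    junction_mask = junction_mask
  ), class = "vjl_group")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A rearrangement set from a data.frame of minimal columns.
make_rs <- function(sequence_alignment, germline_alignment, junction,
                    v_call = "IGHV1-T*01", j_call = "IGHJ1*01",
                    sequence_id = NULL, productive = TRUE,
                    duplicate_count = 1L) {
  n <- length(sequence_alignment)
  df <- data.frame(
    sequence_id = sequence_id %||% sprintf("q%d", seq_len(n)),
    sequence_alignment = sequence_alignment,
    germline_alignment = germline_alignment,
    v_call = v_call, j_call = j_call,
    junction = junction,
    junction_length = nchar(junction),
    productive = productive,
    duplicate_count = duplicate_count,
    stringsAsFactors = FALSE)
  clonespect:::.new_rearrangement_set(df, provenance = list(filters = character(0)))
}

# small simulated repertoire shared by several tests
small_sim <- function(seed = 5L, n = 150, amp = 8) {
  simulate_repertoire(
    sim_params(n_sequences_mean = n, n_sequences_sd = n / 10,
               clone_size_amplitude_mean = amp, clone_size_amplitude_sd = amp / 10),
    seed = seed)
}

run_config <- function(rs, method, target, seed = 3L) {
  assign_clones(rs, method = method, target = target, seed = seed)
}

metrics_for <- function(sim, method, target, seed = 3L) {
  rs <- collapse_identical(suppressMessages(filter_productive(sim$rearrangements)))
  part <- assign_clones(rs, method = method, target = target, seed = seed)
  truth <- stats::setNames(sim$truth$clone_id, sim$truth$sequence_id)
  confusion_metrics(pairwise_confusion(truth[names(part$assignments)],
                                       part$assignments))
}
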