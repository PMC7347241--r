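# Reading, filtering, deduplicating and writing AIRR / Change-O
# rearrangement tables. A rearrangement set is a data.frame (one row per
# sequence) carrying provenance and, after collapsing, a map from every
# original sequence_id to its unique-sequence representative.

.AIRR_REQUIRED <- c("sequence_id", "sequence_alignment", "germline_alignment",
                    "v_call", "j_call", "junction")

.CHANGEO_MAP <- c(
  SEQUENCE_ID       = "sequence_id",
  SEQUENCE_IMGT     = "sequence_alignment",
  GERMLINE_IMGT     = "germline_alignment",
  GERMLINE_IMGT_D_MASK = "germline_alignment",
  V_CALL            = "v_call",
  J_CALL            = "j_call",
  JUNCTION          = "junction",
  JUNCTION_LENGTH   = "junction_length",
  FUNCTIONAL        = "productive",
  DUPCOUNT          = "duplicate_count",
  CLONE             = "clone_id"
)

.new_rearrangement_set <- function(df, provenance = list(),
                                   collapse_map = NULL) {
  structure(df,
            class = c("rearrangement_set", "data.frame"),
            provenance = provenance,
            collapse_map = collapse_map)
}

.rs_attr_keep <- function(rs, df) {
  .new_rearrangement_set(df,
                         provenance = attr(rs, "provenance"),
                         collapse_map = attr(rs, "collapse_map"))
}

.parse_logical_flag <- function(x) {
  if (is.logical(x)) return(x)
  toupper(as.character(x)) %in% c("T", "TRUE", "1", "YES", "Y")
}

#' Read an AIRR or Change-O rearrangement table
#'
#' Reads a tab-delimited rearrangement file into a `rearrangement_set`
#' data.frame. The AIRR dialect uses lowercase AIRR schema column names; the
#' Change-O dialect accepts the uppercase legacy headers (`SEQUENCE_ID`,
#' `SEQUENCE_IMGT`, `GERMLINE_IMGT`, ...) and maps them onto the AIRR names.
#' A missing `junction_length` column is recomputed from `junction`. Records
#' whose junction cannot be located as a contiguous substring of the
#' gap-stripped `sequence_alignment` are dropped with a warning, since every
#' downstream step needs the junction coordinates.
#'
#' @param path path to a tab-delimited rearrangement file.
#' @param dialect `"airr"` (default) or `"changeo"`.
#' @return A `rearrangement_set`: a data.frame with columns `sequence_id`,
#'   `sequence_alignment`, `germline_alignment`, `v_call`, `j_call`,
#'   `junction`, `junction_length`, `productive`, `duplicate_count` (plus any
#'   extra input columns), row order preserved.
#' @examples
#' tsv <- system.file("extdata", "example_airr.tsv", package = "clonespect")
#' rs <- read_rearrangements(tsv)
#' nrow(rs)
#' @export
read_rearrangements <- function(path, dialect = c("airr", "changeo")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character", data.table = FALSE,
                          na.strings = NULL)
  if (nrow(df) == 0L) stop("empty rearrangement file: ", path, call. = FALSE)
  if (dialect == "changeo") {
    hit <- names(df) %in% names(.CHANGEO_MAP)
    names(df)[hit] <- unname(.CHANGEO_MAP[names(df)[hit]])
    names(df)[!hit] <- tolower(names(df)[!hit])
    df <- df[, !duplicated(names(df)), drop = FALSE]
  }
  missing_cols <- setdiff(.AIRR_REQUIRED, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df$sequence_alignment <- toupper(df$sequence_alignment)
  df$germline_alignment <- toupper(df$germline_alignment)
  df$junction <- toupper(df$junction)
  if (!"junction_length" %in% names(df) || all(df$junction_length == "")) {
    df$junction_length <- nchar(df$junction)
  } else {
    df$junction_length <- as.integer(df$junction_length)
    bad <- is.na(df$junction_length)
    df$junction_length[bad] <- nchar(df$junction[bad])
  }
  df$productive <- if ("productive" %in% names(df)) {
    .parse_logical_flag(df$productive)
  } else TRUE
  df$duplicate_count <- if ("duplicate_count" %in% names(df)) {
    n <- suppressWarnings(as.integer(df$duplicate_count))
    ifelse(is.na(n) | n < 1L, 1L, n)
  } else 1L
  bad_len <- nchar(df$sequence_alignment) != nchar(df$germline_alignment)
  if (any(bad_len)) {
    stop("sequence_alignment and germline_alignment lengths differ for: ",
         paste(utils::head(df$sequence_id[bad_len], 3L), collapse = ", "),
         call. = FALSE)
  }
  # junction must be locatable in the gap-stripped sequence
  ungapped <- vapply(df$sequence_alignment, .strip_gaps, "", USE.NAMES = FALSE)
  found <- mapply(function(s, j) {
    nchar(j) > 0L && regexpr(j, s, fixed = TRUE)[[1L]] > 0L
  }, ungapped, df$junction)
  if (any(!found)) {
    warning(sum(!found), " record(s) dropped: junction not found in ",
            "sequence_alignment", call. = FALSE)
    df <- df[found, , drop = FALSE]
    if (nrow(df) == 0L) stop("no records left after junction check",
                             call. = FALSE)
  }
  if (anyDuplicated(df$sequence_id)) {
    stop("duplicated sequence_id in input", call. = FALSE)
  }
  rownames(df) <- NULL
  .new_rearrangement_set(df, provenance = list(path = path, dialect = dialect,
                                               filters = character(0)))
}

#' Keep only productive rearrangements
#'
#' Retains records that (1) are flagged productive/functional, (2) contain no
#' stop codon in the gap-stripped coding frame (frame 1 of the IMGT-gapped
#' alignment, which is codon-aligned by construction), and (3) have a
#' junction length divisible by 3 (in-frame junction). The three criteria are
#' applied conjunctively; counts removed by each are reported via `message()`.
#'
#' @param rs a `rearrangement_set`.
#' @return The filtered `rearrangement_set` (possibly with zero rows).
#' @export
filter_productive <- function(rs) {
  flag_ok <- rs$productive
  frame_ok <- rs$junction_length %% 3L == 0L
  stop_ok <- !vapply(rs$sequence_alignment, .has_stop_codon, logical(1L),
                     USE.NAMES = FALSE)
  keep <- flag_ok & frame_ok & stop_ok
  message(sprintf(
    "filter_productive: removed %d non-functional, %d with stop codon, %d out-of-frame junction; kept %d/%d",
    sum(!flag_ok), sum(flag_ok & !stop_ok),
    sum(flag_ok & stop_ok & !frame_ok), sum(keep), length(keep)))
  out <- rs[keep, , drop = FALSE]
  rownames(out) <- NULL
  prov <- attr(rs, "provenance")
  prov$filters <- union(prov$filters, "productive")
  .new_rearrangement_set(out, provenance = prov,
                         collapse_map = attr(rs, "collapse_map"))
}

#' Collapse identical sequences
#'
#' Merges records with byte-identical `sequence_alignment` strings into one
#' representative (the first occurrence). `duplicate_count` of the
#' representative becomes the sum over merged records, and a map from every
#' original `sequence_id` to its representative id is stored in the
#' `collapse_map` attribute so clone assignments can later be propagated back
#' to all input records. Collapsing keys on the full alignment (not the
#' junction alone) so that distinct V/J mutation patterns stay distinct.
#'
#' @param rs a `rearrangement_set`.
#' @return A `rearrangement_set` of unique sequences.
#' @export
collapse_identical <- function(rs) {
  key <- rs$sequence_alignment
  first <- !duplicated(key)
  rep_id <- rs$sequence_id[first][match(key, key[first])]
  counts <- tapply(rs$duplicate_count, factor(rep_id, levels = rs$sequence_id[first]),
                   sum)
  out <- rs[first, , drop = FALSE]
  out$duplicate_count <- as.integer(counts[out$sequence_id])
  rownames(out) <- NULL
  prev <- attr(rs, "collapse_map")
  cmap <- stats::setNames(rep_id, rs$sequence_id)
  if (!is.null(prev)) {
    # compose with an earlier collapse: original -> old rep -> new rep
    cmap <- stats::setNames(cmap[unname(prev)], names(prev))
  }
  prov <- attr(rs, "provenance")
  prov$filters <- union(prov$filters, "collapse")
  .new_rearrangement_set(out, provenance = prov, collapse_map = cmap)
}

#' Write a clone-annotated rearrangement table
#'
#' Re-emits the input table as AIRR TSV with an added `clone_id` column taken
#' from a clone partition. Records that were collapsed into a representative
#' receive the representative's clone.
#'
#' @param rs the `rearrangement_set` to write (original or collapsed).
#' @param partition a `clone_partition` from [assign_clones()], or a named
#'   character vector `sequence_id -> clone_id`.
#' @param path output file path.
#' @return Invisibly, the written data.frame.
#' @export
write_clones <- function(rs, partition, path) {
  assignments <- if (inherits(partition, "clone_partition")) {
    partition$assignments
  } else partition
  clone <- assignments[rs$sequence_id]
  if (anyNA(clone)) {
    stop("no clone assignment for sequence_id(s): ",
         paste(utils::head(rs$sequence_id[is.na(clone)], 3L), collapse = ", "),
         call. = FALSE)
  }
  out <- as.data.frame(rs)
  out$clone_id <- unname(clone)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "")
  invisible(out)
}
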