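# IUPAC nucleotide ambiguity tables and low-level string helpers shared
# across the package. Gap characters follow IMGT convention: "." for
# IMGT-numbering gaps, "-" for alignment gaps; both are treated identically.

.GAP_CHARS <- c(".", "-")
.STOP_CODONS <- c("TAA", "TAG", "TGA")

# code -> set of plain bases
.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# sorted base set (collapsed to a key) -> code
.IUPAC_FROM_SET <- local({
  keys <- vapply(.IUPAC_SETS, function(s) paste(sort(s), collapse = ""), "")
  stats::setNames(names(.IUPAC_SETS), keys)
})

.is_gap <- function(chars) chars %in% .GAP_CHARS

.is_acgt <- function(chars) chars %in% c("A", "C", "G", "T")

# Split aligned sequences (equal length) into an n x L character matrix.
.char_matrix <- function(strings) {
  n <- length(strings)
  L <- unique(nchar(strings))
  if (length(L) != 1L) {
    stop("aligned sequences must all have the same length", call. = FALSE)
  }
  matrix(unlist(strsplit(toupper(strings), "", fixed = TRUE), use.names = FALSE),
         nrow = n, ncol = L, byrow = TRUE)
}

.strip_gaps <- function(string) {
  gsub("[.\\-]", "", string)
}

# Indices (in alignment coordinates) of the non-gap characters of `string`,
# so that gap-stripped position p corresponds to alignment position map[p].
.ungapped_map <- function(string) {
  chars <- strsplit(string, "", fixed = TRUE)[[1]]
  which(!.is_gap(chars))
}

# TRUE if the in-frame translation (frame 1 of the gap-stripped sequence)
# contains a stop codon. Codons containing non-ACGT characters are skipped.
.has_stop_codon <- function(string) {
  s <- .strip_gaps(toupper(string))
  n_codon <- nchar(s) %/% 3L
  if (n_codon == 0L) return(FALSE)
  starts <- 3L * (seq_len(n_codon) - 1L) + 1L
  codons <- substring(s, starts, starts + 2L)
  any(codons %in% .STOP_CODONS)
}
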