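# 5-mer somatic-hypermutation targeting models: a map from every ACGT 5-mer
# to the mutability of its central base. Used (i) to damp shared mutations
# at mutational hot-spots during clustering and (ii) to place substitutions
# during simulation.

.ALL_5MERS <- local({
  b <- c("A", "C", "G", "T")
  g <- expand.grid(b, b, b, b, b, stringsAsFactors = FALSE)
  sort(apply(g, 1L, paste, collapse = ""))
})

.new_targeting_model <- function(mutability, name) {
  structure(list(mutability = mutability, name = name),
            class = "targeting_model")
}

#' @export
print.targeting_model <- function(x, ...) {
  cat(sprintf("5-mer targeting model '%s': %d motifs, mutability in [%.3g, %.3g]\n",
              x$name, length(x$mutability), min(x$mutability), max(x$mutability)))
  invisible(x)
}

#' Uniform 5-mer targeting model
#'
#' Every 5-mer gets the same mutability. With `value = 0` the damping matrix
#' degenerates to 1 everywhere (damping disabled).
#'
#' @param value mutability in \[0, 1\] assigned to all 1024 motifs.
#' @return A `targeting_model`.
#' @export
uniform_targeting_model <- function(value = 0) {
  if (value < 0 || value > 1) stop("mutability must be in [0,1]", call. = FALSE)
  .new_targeting_model(stats::setNames(rep(value, length(.ALL_5MERS)),
                                       .ALL_5MERS),
                       sprintf("uniform:%g", value))
}

#' Synthetic hot-/cold-spot targeting model
#'
#' A built-in model encoding the classic SHM targeting hierarchy: WRC/GYW
#' hot-spots (W=A/T, R=A/G; mutable position the C/G) and WA/TW hot-spots get
#' elevated mutability, SYC/GRS cold-spots get depressed mutability, all
#' other motifs a baseline. This is a synthetic stand-in with the qualitative
#' structure of published 5-mer models, not a fit to data.
#'
#' @param hot,warm,base,cold mutabilities for WRC/GYW, WA/TW, neutral and
#'   SYC/GRS motifs.
#' @return A `targeting_model`.
#' @export
hotspot_targeting_model <- function(hot = 0.30, warm = 0.15, base = 0.05,
                                    cold = 0.01) {
  vals <- c(hot, warm, base, cold)
  if (any(vals < 0 | vals > 1)) stop("mutability must be in [0,1]", call. = FALSE)
  mut <- stats::setNames(rep(base, length(.ALL_5MERS)), .ALL_5MERS)
  c1 <- substr(.ALL_5MERS, 1L, 1L); c2 <- substr(.ALL_5MERS, 2L, 2L)
  c3 <- substr(.ALL_5MERS, 3L, 3L); c4 <- substr(.ALL_5MERS, 4L, 4L)
  c5 <- substr(.ALL_5MERS, 5L, 5L)
  w <- c("A", "T"); r <- c("A", "G"); y <- c("C", "T"); s <- c("C", "G")
  # central base is position 3 of the 5-mer
  wrc <- c3 == "C" & c2 %in% r & c1 %in% w          # W R C . .
  gyw <- c3 == "G" & c4 %in% y & c5 %in% w          # . . G Y W
  wa  <- c3 == "A" & c2 %in% w                      # W A (TA/AA)
  tw  <- c3 == "T" & c4 %in% w                      # T W
  syc <- c3 == "C" & c2 %in% y & c1 %in% s          # S Y C
  grs <- c3 == "G" & c4 %in% r & c5 %in% s          # G R S
  mut[wa | tw] <- warm
  mut[syc | grs] <- cold
  mut[wrc | gyw] <- hot
  .new_targeting_model(mut, "synthetic-hotspot")
}

#' Load a 5-mer targeting model from a TSV file
#'
#' Expects a tab-delimited table with columns `motif` (length-5 ACGT string)
#' and `mutability` (in \[0, 1\]), as in S5F-style model tables. Motifs absent
#' from the file get mutability 0 (no damping contribution).
#'
#' @param path path to the model table.
#' @param name model name (defaults to the file name).
#' @return A `targeting_model`.
#' @export
load_targeting_model <- function(path, name = basename(path)) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  if (!all(c("motif", "mutability") %in% names(df))) {
    stop("targeting model table needs columns 'motif' and 'mutability'",
         call. = FALSE)
  }
  motif <- toupper(as.character(df$motif))
  val <- as.numeric(df$mutability)
  ok <- !is.na(val)
  motif <- motif[ok]; val <- val[ok]
  if (any(val < 0 | val > 1)) {
    stop("mutability values must be in [0,1]", call. = FALSE)
  }
  bad <- nchar(motif) != 5L | grepl("[^ACGT]", motif)
  if (any(bad)) stop("motifs must be length-5 ACGT strings", call. = FALSE)
  mut <- stats::setNames(rep(0, length(.ALL_5MERS)), .ALL_5MERS)
  mut[motif] <- val
  .new_targeting_model(mut, name)
}

#' Mutability of one germline position
#'
#' Extracts the 5-mer centred at alignment position `pos` from the
#' gap-stripped germline and looks up its mutability. IUPAC ambiguity codes
#' in the window are averaged over all compatible ACGT 5-mers; a window that
#' runs off either end of the sequence, or contains `N` (or a character with
#' no IUPAC expansion), yields 0.
#'
#' @param tm a `targeting_model`.
#' @param germline IUPAC nucleotide string (may contain gaps).
#' @param pos 1-based alignment position of the central base.
#' @return Mutability in \[0, 1\].
#' @export
motif_mutability <- function(tm, germline, pos) {
  chars <- strsplit(toupper(germline), "", fixed = TRUE)[[1L]]
  map <- which(!.is_gap(chars))
  p <- match(pos, map)            # gap-stripped index of this position
  if (is.na(p) || p < 3L || p > length(map) - 2L) return(0)
  window <- chars[map[seq.int(p - 2L, p + 2L)]]
  if (any(window == "N")) return(0)
  sets <- .IUPAC_SETS[window]
  if (any(vapply(sets, is.null, logical(1L)))) return(0)
  motifs <- apply(expand.grid(sets, stringsAsFactors = FALSE), 1L,
                  paste, collapse = "")
  mean(tm$mutability[motifs])
}

# Per-alignment-position mutability averaged over a set of germline alleles
# (vectorised over positions; used by the damping matrix and the simulator).
.position_mutability <- function(tm, germlines, L) {
  acc <- numeric(L)
  for (g in germlines) {
    chars <- strsplit(toupper(g), "", fixed = TRUE)[[1L]]
    map <- which(!.is_gap(chars))
    m <- length(map)
    mu <- numeric(L)
    if (m >= 5L) {
      centers <- seq.int(3L, m - 2L)
      s <- paste(chars[map], collapse = "")
      motifs <- substring(s, centers - 2L, centers + 2L)
      plain <- !grepl("[^ACGT]", motifs)
      vals <- numeric(length(centers))
      vals[plain] <- tm$mutability[motifs[plain]]
      amb <- which(!plain)
      for (i in amb) {
        vals[i] <- motif_mutability(tm, g, map[centers[i]])
      }
      mu[map[centers]] <- vals
    }
    acc <- acc + mu
  }
  acc / length(germlines)
}
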