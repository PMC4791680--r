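#' Canonical representative of a repeat-motif class
#'
#' Tandem-repeat units that are rotations of each other, or rotations of each
#' other's reverse complement, describe the same microsatellite (`AAAG`,
#' `AGAA`, `CTTT`, ...). The canonical motif is the lexicographically smallest
#' string among all rotations of the motif and all rotations of its reverse
#' complement, which gives every equivalence class a single deterministic
#' label.
#'
#' @param motif character vector of repeat units over `A,C,G,T`.
#' @return character vector of canonical motifs.
#' @examples
#' canonical_motif("GAAA")  # "AAAG"
#' canonical_motif("CTTT")  # "AAAG"
#' @export
canonical_motif <- function(motif) {
  vapply(motif, function(m) {
    if (grepl("[^ACGT]", m)) {
      stop("motif must be over A,C,G,T (got '", m, "')", call. = FALSE)
    }
    p <- nchar(m)
    rc <- revcomp(m)
    rot <- function(s) vapply(seq_len(p) - 1L, function(k) {
      paste0(substr(s, k + 1L, p), substr(s, 1L, k))
    }, character(1))
    min(c(rot(m), rot(rc)))
  }, character(1), USE.NAMES = FALSE)
}

repeat_locus_frame <- function() {
  data.frame(scaffold = character(0), start = integer(0), end = integer(0),
             motif = character(0), canonical = character(0),
             period = integer(0), n_repeats = integer(0),
             stringsAsFactors = FALSE)
}

#' Find perfect tandem repeats in one sequence
#'
#' Reports every maximal run of at least `min_repeats` exact copies of a
#' `period`-length unit. Runs are maximal: they cannot be extended on either
#' side by a full or partial copy without breaking exactness. A run is
#' reported once, anchored at its leftmost start; the reported `motif` is the
#' unit beginning at that position and `canonical` is its class label from
#' [canonical_motif()]. Partial trailing copies are not counted in
#' `n_repeats` and not included in `[start, end)`.
#'
#' @param sequence a DNA string over `A,C,G,T,N` (uppercase).
#' @param period repeat unit length in bp (default 4, i.e. tetranucleotide).
#' @param min_repeats minimum number of whole tandem copies (default 8).
#' @param scaffold_id id recorded in the output (default `NA`).
#' @return data.frame with columns `scaffold`, `start`, `end` (0-based
#'   half-open), `motif`, `canonical`, `period`, `n_repeats`, sorted by
#'   `(start, end)`.
#' @details Runs containing `N` (or any non-ACGT character) are excluded, as
#'   are runs whose unit is a homopolymer (e.g. `AAAA` for period 4 — a
#'   period-1 repeat, not a tetranucleotide motif).
#' @export
find_perfect_repeats <- function(sequence, period = 4L, min_repeats = 8L,
                                 scaffold_id = NA_character_) {
  stopifnot(length(sequence) == 1, period >= 1, min_repeats >= 2)
  period <- as.integer(period)
  min_repeats <- as.integer(min_repeats)
  n <- nchar(sequence)
  if (n < period * min_repeats) return(repeat_locus_frame())
  x <- charToRaw(sequence)
  valid <- x %in% charToRaw("ACGT")
  idx <- seq_len(n - period)
  # eq[k]: position k matches position k+period and both are unambiguous bases
  eq <- (x[idx] == x[idx + period]) & valid[idx] & valid[idx + period]
  r <- rle(eq)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  keep <- r$values & r$lengths >= period * (min_repeats - 1L)
  if (!any(keep)) return(repeat_locus_frame())
  a <- run_start[keep]
  m <- r$lengths[keep] %/% period + 1L            # whole copies from leftmost start
  motif <- substring(sequence, a, a + period - 1L)
  homopolymer <- vapply(strsplit(motif, "", fixed = TRUE),
                        function(ch) length(unique(ch)) == 1L, logical(1))
  ok <- m >= min_repeats & !homopolymer
  if (!any(ok)) return(repeat_locus_frame())
  a <- a[ok]; m <- m[ok]; motif <- motif[ok]
  out <- data.frame(
    scaffold = scaffold_id,
    start = a - 1L,                                # to 0-based
    end = a - 1L + m * period,
    motif = motif,
    canonical = canonical_motif(motif),
    period = period,
    n_repeats = m,
    stringsAsFactors = FALSE
  )
  out[order(out$start, out$end), , drop = FALSE]
}

#' Screen scaffolds for microsatellite loci
#'
#' Runs [find_perfect_repeats()] over every scaffold longer than
#' `min_scaffold_len` and concatenates the results. The defaults reproduce
#' the screening rule used for reference-mapped rodent scaffolds:
#' tetranucleotide motifs with at least 8 tandem copies on scaffolds longer
#' than 1 Mbp.
#'
#' @param sequences named character vector of scaffold sequences (as from
#'   [read_fasta()]).
#' @param min_scaffold_len only scaffolds strictly longer than this are
#'   scanned (default 1e6 bp).
#' @param period,min_repeats screening rule, passed to
#'   [find_perfect_repeats()].
#' @return data.frame of repeat loci (see [find_perfect_repeats()]) with a
#'   `"summary"` attribute: a list with `scaffolds_total`,
#'   `scaffolds_scanned`, `loci_found` and `loci_per_motif` (a table of
#'   canonical motifs). The summary is also logged.
#' @export
screen_scaffolds <- function(sequences, min_scaffold_len = 1e6,
                             period = 4L, min_repeats = 8L) {
  stopifnot(min_scaffold_len >= 0)
  if (is.null(names(sequences)) && length(sequences) > 0) {
    stop("sequences must be named by scaffold id", call. = FALSE)
  }
  long <- nchar(sequences) > min_scaffold_len
  loci <- lapply(names(sequences)[long], function(id) {
    find_perfect_repeats(sequences[[id]], period = period,
                         min_repeats = min_repeats, scaffold_id = id)
  })
  out <- if (length(loci)) do.call(rbind, loci) else repeat_locus_frame()
  rownames(out) <- NULL
  summary <- list(
    scaffolds_total = length(sequences),
    scaffolds_scanned = sum(long),
    loci_found = nrow(out),
    loci_per_motif = if (nrow(out)) table(out$canonical) else table(character(0))
  )
  msat_log("screened ", summary$scaffolds_scanned, "/", summary$scaffolds_total,
           " scaffold(s) > ", format(min_scaffold_len, scientific = FALSE),
           " bp; found ", summary$loci_found, " repeat locus/loci")
  attr(out, "summary") <- summary
  out
}
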