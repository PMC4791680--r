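#' Read a 12-column tabular homology-search result
#'
#' Parses the standard 12-column tabular output of BLAST-family tools
#' (`qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore`) and applies the E-value threshold used for translated
#' searches of marker flanking fragments.
#'
#' @param path path to the tab-separated hit file (no header).
#' @param max_evalue keep hits with `evalue <= max_evalue` (default `1e-6`).
#' @return data.frame with columns `query_id`, `subject_id`,
#'   `percent_identity`, `align_length`, `mismatches`, `gap_opens`,
#'   `query_start`, `query_end`, `subject_start`, `subject_end`, `evalue`,
#'   `bitscore`, `gene_symbol`. Alignment coordinates are kept exactly as the
#'   producer wrote them (1-based inclusive). `gene_symbol` is parsed from the
#'   subject id (see [normalize_symbol()]).
#' @details The threshold is inclusive: a hit at exactly `max_evalue` is
#'   retained. Lines with a column count other than 12 are an error reporting
#'   the line number.
#' @export
read_blast_tab <- function(path, max_evalue = 1e-6) {
  stopifnot(is.numeric(max_evalue), max_evalue >= 0)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12)) {
    bad <- which(keep)[which(nf != 12)[1]]
    stop("line ", bad, ": expected 12 tab-separated columns, got ",
         nf[which(nf != 12)[1]], call. = FALSE)
  }
  if (length(fields) == 0) {
    hits <- empty_blast_frame()
    return(hits)
  }
  m <- do.call(rbind, fields)
  hits <- data.frame(
    query_id = m[, 1],
    subject_id = m[, 2],
    percent_identity = as.numeric(m[, 3]),
    align_length = as.integer(m[, 4]),
    mismatches = as.integer(m[, 5]),
    gap_opens = as.integer(m[, 6]),
    query_start = as.integer(m[, 7]),
    query_end = as.integer(m[, 8]),
    subject_start = as.integer(m[, 9]),
    subject_end = as.integer(m[, 10]),
    evalue = as.numeric(m[, 11]),
    bitscore = as.numeric(m[, 12]),
    stringsAsFactors = FALSE
  )
  if (any(is.na(hits$evalue)) || any(hits$evalue < 0)) {
    stop("invalid E-value in ", path, call. = FALSE)
  }
  hits <- hits[hits$evalue <= max_evalue, , drop = FALSE]
  hits$gene_symbol <- vapply(hits$subject_id, parse_subject_symbol, character(1),
                             USE.NAMES = FALSE)
  rownames(hits) <- NULL
  hits
}

empty_blast_frame <- function() {
  data.frame(query_id = character(0), subject_id = character(0),
             percent_identity = numeric(0), align_length = integer(0),
             mismatches = integer(0), gap_opens = integer(0),
             query_start = integer(0), query_end = integer(0),
             subject_start = integer(0), subject_end = integer(0),
             evalue = numeric(0), bitscore = numeric(0),
             gene_symbol = character(0), stringsAsFactors = FALSE)
}

# Pull a plausible gene symbol out of a BLAST subject id: take the last
# non-empty pipe-delimited token (handles "sp|P12345|Nrxn1" style ids).
parse_subject_symbol <- function(subject_id) {
  toks <- strsplit(subject_id, "|", fixed = TRUE)[[1]]
  toks <- toks[nzchar(toks)]
  if (length(toks) == 0) return(NA_character_)
  toks[length(toks)]
}

#' Normalize a gene symbol for cross-source comparison
#'
#' Annotation attributes and homology-search subject descriptions spell the
#' same gene differently (case, isoform suffixes), so symbols are compared
#' after normalization: uppercase, with one trailing `.N` or `-N` isoform
#' suffix removed.
#'
#' @param symbols character vector of symbols.
#' @return character vector of normalized symbols.
#' @examples
#' normalize_symbol(c("Nrxn1", "NRXN1-1", "nrxn1.2"))  # all "NRXN1"
#' @export
normalize_symbol <- function(symbols) {
  toupper(sub("[.-][0-9]+$", "", symbols))
}
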