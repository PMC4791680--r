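#' Read scaffold sequences from a FASTA file
#'
#' Reads a (possibly lowercase) FASTA file into a named character vector of
#' uppercase DNA sequences over `A,C,G,T,N`. IUPAC ambiguity codes other than
#' `N` (e.g. `R`, `Y`, `S`) are mapped to `N` — mapping-derived consensus
#' scaffolds can contain them — and the number of substitutions is logged.
#'
#' @param path path to a FASTA file.
#' @return named character vector; names are record ids (first whitespace
#'   token of the header), values are uppercase sequences.
#' @details Duplicate record ids are an error. An empty file returns an empty
#'   vector with a warning. Characters outside the IUPAC DNA alphabet are also
#'   mapped to `N`.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) {
                    if (file.exists(path) && file.size(path) == 0) return(NULL)
                    stop("failed to read FASTA '", path, "': ",
                         conditionMessage(e), call. = FALSE)
                  })
  if (is.null(set) || length(set) == 0) {
    warning("empty FASTA file: ", path, call. = FALSE)
    return(setNames(character(0), character(0)))
  }
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop("duplicate id ", dup[1], " in ", path, call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  normalize_dna(seqs)
}

# Map everything outside {A,C,G,T,N} to N, logging the substitution count.
normalize_dna <- function(seqs) {
  cleaned <- gsub("[^ACGTN]", "N", seqs)
  n_sub <- sum(vapply(seq_along(seqs), function(i) {
    sum(charToRaw(seqs[[i]]) != charToRaw(cleaned[[i]]))
  }, integer(1)))
  if (n_sub > 0) {
    msat_log("normalized ", n_sub, " ambiguity base(s) to N")
  }
  cleaned
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences (as from [read_fasta()]).
#' @param path output path.
#' @param width line width for wrapping (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Write intervals to a BED file
#'
#' Writes 0-based half-open intervals (the package's internal convention,
#' which is also BED's) as a headerless tab-separated file.
#'
#' @param intervals data.frame with columns `scaffold`, `start`, `end` and
#'   optionally `name`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  cols <- c("scaffold", "start", "end")
  stopifnot(all(cols %in% names(intervals)))
  out <- intervals[, cols]
  if ("name" %in% names(intervals)) out$name <- intervals$name
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file of intervals
#'
#' @param path path to a headerless BED3/BED4 file.
#' @return data.frame with columns `scaffold`, `start`, `end` and, when
#'   present, `name`; coordinates stay 0-based half-open.
#' @export
read_bed <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df)[1:3] <- c("scaffold", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df
}
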