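#' Read a cross-species amplification score table
#'
#' Expects a CSV with columns `species,sample,locus,success` where `success`
#' is 1 (a product of the expected size with no smearing), 0 (failure), or
#' blank/`NA` (untested). Success is a wet-lab judgment supplied as input,
#' never computed here; this module is bookkeeping over those labels.
#'
#' @param path path to the CSV file.
#' @return data.frame of class `amplification_matrix` with `species` and
#'   `loci` attributes recording input order.
#' @export
read_amplification <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  amplification_matrix(df)
}

#' Amplification matrix constructor
#'
#' @param df data.frame with columns `species`, `sample`, `locus`, `success`
#'   (`0`, `1` or `NA` for untested).
#' @return data.frame of class `amplification_matrix`.
#' @export
amplification_matrix <- function(df) {
  stopifnot(all(c("species", "sample", "locus", "success") %in% names(df)))
  bad <- !is.na(df$success) & !df$success %in% c(0, 1)
  if (any(bad)) stop("success must be 0, 1 or NA (row ", which(bad)[1], ")",
                     call. = FALSE)
  structure(df, class = c("amplification_matrix", "data.frame"),
            species = unique(df$species), loci = unique(df$locus))
}

#' Amplification success rate for one species and locus
#'
#' @param matrix an [amplification_matrix].
#' @param species,locus which cell of the species-by-locus design to score.
#' @return successes / tested, or `NA` if no sample was tested (untested
#'   samples never enter the denominator).
#' @export
success_rate <- function(matrix, species, locus) {
  sub <- matrix[matrix$species == species & matrix$locus == locus, ,
                drop = FALSE]
  tested <- sub$success[!is.na(sub$success)]
  if (length(tested) == 0) return(NA_real_)
  mean(tested)
}

# per-locus success rates for one species, named by locus
species_rates <- function(matrix, species) {
  loci <- attr(matrix, "loci")
  vapply(loci, function(l) success_rate(matrix, species, l), numeric(1))
}

#' Number of loci amplifying at or above a success-rate threshold
#'
#' @param matrix an [amplification_matrix].
#' @param species species id.
#' @param threshold success-rate threshold in `[0, 1]`; the comparison is
#'   inclusive ("80\% or better"). Loci with no tested sample are excluded
#'   even at threshold 0.
#' @return integer count of loci with `success_rate >= threshold`.
#' @export
loci_at_threshold <- function(matrix, species, threshold) {
  stopifnot(threshold >= 0, threshold <= 1)
  rates <- species_rates(matrix, species)
  sum(!is.na(rates) & rates >= threshold)
}

#' Per-species amplification counts at multiple thresholds
#'
#' Tabulates, for every species, the number of loci amplifying at each
#' success-rate threshold, ranked by the count at the highest threshold
#' (ties keep species input order).
#'
#' @param matrix an [amplification_matrix].
#' @param thresholds numeric vector of thresholds (default `c(0.8, 0.4)`).
#' @param path optional path; when given, the table is also written as TSV.
#' @return data.frame with a `species` column and one `n_ge_<pct>` count
#'   column per threshold, ordered by rank.
#' @export
species_table <- function(matrix, thresholds = c(0.8, 0.4), path = NULL) {
  species <- attr(matrix, "species")
  stopifnot(length(species) >= 1)
  counts <- vapply(thresholds, function(t) {
    vapply(species, function(s) loci_at_threshold(matrix, s, t), integer(1))
  }, integer(length(species)))
  dim(counts) <- c(length(species), length(thresholds))
  colnames(counts) <- paste0("n_ge_", round(100 * thresholds))
  out <- data.frame(species = species, counts, stringsAsFactors = FALSE,
                    row.names = NULL)
  top <- counts[, which.max(thresholds), drop = TRUE]
  # stable sort: ties preserve species input order
  out <- out[order(-top), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(path)) {
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
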