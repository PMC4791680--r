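#' Primer-design parameter set
#'
#' Collects the constraints handed to an external thermodynamic primer
#' designer (Primer3) and used by [designability_check()]. Defaults mirror a
#' standard microsatellite-genotyping setup: primers of 20-24 bp, optimum
#' melting temperature 57 degrees C in a 54-65 range, and a maximum product
#' size of 450 bp so amplicons remain scorable on a capillary sequencer.
#'
#' @param primer_len_min,primer_len_max primer length bounds in bp (20, 24).
#' @param tm_opt,tm_min,tm_max melting temperature optimum and range in
#'   degrees C (57, 54, 65).
#' @param max_product maximum amplicon size in bp (450).
#' @param flank_len flanking sequence extracted on each side of the repeat
#'   for primer placement, in bp (200).
#' @param max_n_fraction maximum tolerated fraction of `N` in a flank (0.2);
#'   mapped-consensus scaffolds can carry gap runs into flanks.
#' @return an object of class `primer_params`.
#' @export
primer_params <- function(primer_len_min = 20L, primer_len_max = 24L,
                          tm_opt = 57, tm_min = 54, tm_max = 65,
                          max_product = 450L, flank_len = 200L,
                          max_n_fraction = 0.2) {
  stopifnot(primer_len_min <= primer_len_max,
            tm_min <= tm_opt, tm_opt <= tm_max,
            max_product > 0, flank_len >= 0,
            max_n_fraction >= 0, max_n_fraction <= 1)
  structure(list(primer_len_min = as.integer(primer_len_min),
                 primer_len_max = as.integer(primer_len_max),
                 tm_opt = tm_opt, tm_min = tm_min, tm_max = tm_max,
                 max_product = as.integer(max_product),
                 flank_len = as.integer(flank_len),
                 max_n_fraction = max_n_fraction),
            class = "primer_params")
}

#' @export
print.primer_params <- function(x, ...) {
  cat(sprintf(paste0("<primer_params> primer %d-%d bp, Tm %g (%g-%g) C, ",
                     "max product %d bp, flank %d bp, max N fraction %g\n"),
              x$primer_len_min, x$primer_len_max, x$tm_opt, x$tm_min, x$tm_max,
              x$max_product, x$flank_len, x$max_n_fraction))
  invisible(x)
}

#' Extract flanking regions around a repeat locus
#'
#' Builds a marker candidate from a repeat locus: the `flank_len` bases on
#' each side of the repeat (clipped at scaffold ends, with clipping recorded
#' in `reason`). A candidate whose clipped flank is shorter than
#' `primer_len_max` cannot hold a primer and is marked not designable.
#'
#' @param sequence the scaffold sequence containing the locus.
#' @param locus one row of a repeat-locus data.frame
#'   ([find_perfect_repeats()]).
#' @param flank_len flank length in bp (default 200).
#' @param primer_len_max longest primer that must fit in a flank (default 24).
#' @return a one-row data.frame: the locus columns plus `left_flank`,
#'   `right_flank`, `left_clipped`, `right_clipped`, `designable`, `reason`,
#'   `tag`, `expected_product_min`, `expected_product_max` (the product-size
#'   columns are filled by [designability_check()]).
#' @export
extract_flanks <- function(sequence, locus, flank_len = 200L,
                           primer_len_max = 24L) {
  stopifnot(nrow(locus) == 1)
  n <- nchar(sequence)
  if (locus$start < 0 || locus$end > n) {
    stop("locus [", locus$start, ",", locus$end, ") outside scaffold of length ",
         n, call. = FALSE)
  }
  left_from <- max(0L, locus$start - flank_len)
  left <- substr(sequence, left_from + 1L, locus$start)       # [left_from, start)
  right_to <- min(n, locus$end + flank_len)
  right <- substr(sequence, locus$end + 1L, right_to)         # [end, right_to)
  left_clipped <- nchar(left) < flank_len
  right_clipped <- nchar(right) < flank_len
  reason <- character(0)
  if (left_clipped) reason <- c(reason, "left flank clipped at scaffold end")
  if (right_clipped) reason <- c(reason, "right flank clipped at scaffold end")
  designable <- TRUE
  if (nchar(left) < primer_len_max) {
    designable <- FALSE
    reason <- c(reason, "left flank too short")
  }
  if (nchar(right) < primer_len_max) {
    designable <- FALSE
    reason <- c(reason, "right flank too short")
  }
  cand <- as.data.frame(locus, stringsAsFactors = FALSE)
  cand$left_flank <- left
  cand$right_flank <- right
  cand$left_clipped <- left_clipped
  cand$right_clipped <- right_clipped
  cand$designable <- designable
  cand$reason <- paste(reason, collapse = "; ")
  cand$tag <- "none"
  cand$expected_product_min <- NA_integer_
  cand$expected_product_max <- NA_integer_
  rownames(cand) <- NULL
  cand
}

#' Build marker candidates for a set of loci
#'
#' Convenience wrapper: [extract_flanks()] then [designability_check()] for
#' every locus.
#'
#' @param sequences named character vector of scaffolds.
#' @param loci repeat-locus data.frame ([screen_scaffolds()]).
#' @param params a [primer_params()] object.
#' @return data.frame of marker candidates, one row per locus.
#' @export
build_candidates <- function(sequences, loci, params = primer_params()) {
  stopifnot(inherits(params, "primer_params"))
  rows <- lapply(seq_len(nrow(loci)), function(i) {
    l <- loci[i, , drop = FALSE]
    extract_flanks(sequences[[l$scaffold]], l, flank_len = params$flank_len,
                   primer_len_max = params$primer_len_max)
  })
  cand <- do.call(rbind, rows)
  designability_check(cand, params)
}

# longest run of non-N characters in a string
longest_clean_run <- function(s) {
  if (!nzchar(s)) return(0L)
  max(nchar(strsplit(s, "N", fixed = TRUE)[[1]]), 0L)
}

#' Check whether a primer pair can be designed around a candidate
#'
#' A candidate is designable when (a) each flank contains at least
#' `primer_len_max` contiguous unambiguous (non-`N`) bases, (b) the `N`
#' fraction of each flank is at most `max_n_fraction`, and (c) the repeat
#' plus two minimum-length primers fits the maximum product size
#' (`repeat length + 2 * primer_len_min <= max_product`). Candidates already
#' failed by [extract_flanks()] stay failed. The minimal and maximal
#' achievable product sizes (shortest primers flush with the repeat vs. the
#' product-size cap) are recorded.
#'
#' @param candidates data.frame from [extract_flanks()] /
#'   [build_candidates()].
#' @param params a [primer_params()] object.
#' @return `candidates` with `designable`, `reason`,
#'   `expected_product_min`, `expected_product_max` updated.
#' @export
designability_check <- function(candidates, params = primer_params()) {
  stopifnot(inherits(params, "primer_params"))
  for (i in seq_len(nrow(candidates))) {
    reason <- candidates$reason[i]
    ok <- candidates$designable[i]
    fail <- function(why) {
      ok <<- FALSE
      reason <<- if (nzchar(reason)) paste(reason, why, sep = "; ") else why
    }
    rep_len <- candidates$end[i] - candidates$start[i]
    for (side in c("left", "right")) {
      fl <- candidates[[paste0(side, "_flank")]][i]
      if (longest_clean_run(fl) < params$primer_len_max) {
        fail(paste(side, "flank lacks", params$primer_len_max,
                   "contiguous unambiguous bases"))
      } else if (nzchar(fl) &&
                 lengths(regmatches(fl, gregexpr("N", fl)))[1] / nchar(fl) >
                 params$max_n_fraction) {
        fail(paste(side, "flank ambiguity"))
      }
    }
    min_product <- rep_len + 2L * params$primer_len_min
    if (min_product > params$max_product) {
      fail(sprintf("repeat too long for product cap (%d + 2x%d > %d)",
                   rep_len, params$primer_len_min, params$max_product))
    }
    candidates$designable[i] <- ok
    candidates$reason[i] <- reason
    candidates$expected_product_min[i] <- min_product
    candidates$expected_product_max[i] <- params$max_product
  }
  candidates
}

#' Universal 5' tag sequences
#'
#' The two universal tags appended to one primer of each pair so a third,
#' fluorescently labeled primer can be used in genotyping PCR.
#' @format named character vector with entries `M13R`
#'   (`GGAAACAGCTATGACCAT`, 18 bp) and `CAG` (`CAGTCGGGCGTCATCA`, 16 bp).
#' @export
tag_sequences <- c(M13R = "GGAAACAGCTATGACCAT", CAG = "CAGTCGGGCGTCATCA")

#' Prepend a universal tag to a primer sequence
#'
#' @param primer_seq primer sequence (5' to 3').
#' @param tag_name `"M13R"` or `"CAG"`.
#' @return the tagged primer: tag sequence concatenated 5' of the primer.
#'   Expected product sizes downstream grow by the tag length.
#' @examples
#' add_tag("ACGTACGTACGTACGTACGT", "M13R")
#' @export
add_tag <- function(primer_seq, tag_name) {
  if (!tag_name %in% names(tag_sequences)) {
    stop("unknown tag '", tag_name, "'; available: ",
         paste(names(tag_sequences), collapse = ", "), call. = FALSE)
  }
  paste0(tag_sequences[[tag_name]], primer_seq)
}

#' Select a stratified random marker panel
#'
#' Draws, for each group (typically the model-genome chromosome a scaffold
#' maps to), a uniform random number of designable candidates between `k_min`
#' and `min(k_max, available)`, without replacement. Groups listed in
#' `exclude_groups` contribute nothing; groups with fewer than `k_min`
#' designable candidates contribute all of them with a logged warning. The
#' draw is deterministic for a fixed `seed`.
#'
#' @param candidates marker-candidate data.frame ([build_candidates()]).
#' @param groups character vector, one group label per candidate row.
#' @param k_min,k_max per-group panel size bounds (defaults 2 and 5).
#' @param exclude_groups group labels to skip entirely (e.g. chromosome 7 and
#'   the sex chromosomes).
#' @param seed integer seed for the draw (required for reproducibility).
#' @return the selected rows of `candidates`, with a `group` column, in group
#'   order.
#' @export
select_panel <- function(candidates, groups, k_min = 2L, k_max = 5L,
                         exclude_groups = character(0), seed) {
  stopifnot(k_min <= k_max, length(groups) == nrow(candidates))
  if (!missing(seed)) set.seed(seed)
  candidates$group <- as.character(groups)
  pool <- candidates[candidates$designable &
                       !candidates$group %in% exclude_groups, , drop = FALSE]
  all_groups <- setdiff(unique(candidates$group), exclude_groups)
  picked <- lapply(all_groups, function(g) {
    rows <- which(pool$group == g)
    if (length(rows) < k_min) {
      warning("group ", g, ": only ", length(rows),
              " designable candidate(s), fewer than k_min = ", k_min,
              call. = FALSE)
      return(pool[rows, , drop = FALSE])
    }
    ks <- seq.int(k_min, min(k_max, length(rows)))
    k <- ks[sample.int(length(ks), 1L)]
    pool[sort(rows[sample.int(length(rows), k)]), , drop = FALSE]
  })
  out <- do.call(rbind, picked)
  if (is.null(out)) out <- cbind(candidates[0, , drop = FALSE])
  rownames(out) <- NULL
  out
}
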