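#' Allele counts and frequencies at one locus
#'
#' @param table a [genotype_table].
#' @param locus locus id.
#' @return list with `N` (genotyped individuals, missing calls excluded),
#'   `freqs` (named numeric vector of allele frequencies from the `2N` allele
#'   copies, summing to 1), `size_range` (min and max allele size) and `N_A`
#'   (number of distinct alleles).
#' @details A locus with no non-missing call is an error naming the locus.
#' @export
allele_stats <- function(table, locus) {
  calls <- locus_calls(table, locus)
  calls <- calls[!is.na(calls$allele1), , drop = FALSE]
  if (nrow(calls) == 0) {
    stop("locus ", locus, ": all genotypes missing", call. = FALSE)
  }
  copies <- c(calls$allele1, calls$allele2)
  counts <- table(copies)
  freqs <- as.numeric(counts) / length(copies)
  names(freqs) <- names(counts)
  list(N = nrow(calls), freqs = freqs,
       size_range = c(min(copies), max(copies)), N_A = length(freqs))
}

#' Observed heterozygosity
#'
#' Fraction of genotyped individuals that are heterozygous at the locus.
#'
#' @inheritParams allele_stats
#' @return numeric in `[0, 1]`.
#' @export
observed_het <- function(table, locus) {
  calls <- locus_calls(table, locus)
  calls <- calls[!is.na(calls$allele1), , drop = FALSE]
  if (nrow(calls) == 0) {
    stop("locus ", locus, ": all genotypes missing", call. = FALSE)
  }
  mean(calls$allele1 != calls$allele2)
}

#' Unbiased expected heterozygosity
#'
#' Nei's (1978) small-sample-corrected expected heterozygosity,
#' `H_E = 2N/(2N - 1) * (1 - sum(p_i^2))`, the estimator used by standard
#' marker-characterization software. For `N = 1` the correction is undefined
#' (factor 2/1 would exceed 1), so the uncorrected `1 - sum(p_i^2)` is
#' returned with a warning.
#'
#' @param freqs numeric vector of allele frequencies summing to 1.
#' @param N number of genotyped individuals the frequencies were estimated
#'   from.
#' @param correct apply the small-sample correction (default `TRUE`; set
#'   `FALSE` for the plain gene-diversity estimator).
#' @return numeric in `[0, 1]`.
#' @export
unbiased_expected_het <- function(freqs, N, correct = TRUE) {
  stopifnot(N >= 1, all(freqs >= 0))
  if (abs(sum(freqs) - 1) > 1e-8) {
    stop("allele frequencies must sum to 1", call. = FALSE)
  }
  d <- 1 - sum(freqs^2)
  if (!correct) return(d)
  if (N == 1) {
    warning("N = 1: returning uncorrected gene diversity", call. = FALSE)
    return(d)
  }
  (2 * N) / (2 * N - 1) * d
}

# --- exact Hardy-Weinberg probability test -------------------------------
#
# Conditional on the allele counts a_1..a_k (2N copies), the probability of a
# genotype-count configuration {n_ij} under random union of gametes is
#
#   P({n_ij}) = N! * prod_k a_k! * 2^h / ( (2N)! * prod_{i<=j} n_ij! )
#
# with h the number of heterozygotes. The p-value is the total probability
# of configurations no more probable than the observed one.

# log-probability of a configuration given log-constant, het count and
# sum of lfactorial(n_ij)
hwe_log_const <- function(N, a) {
  lfactorial(N) + sum(lfactorial(a)) - lfactorial(2 * N)
}

# Enumerate log-probabilities of all configurations with allele counts `a`.
# Returns NULL if the configuration count exceeds `cap`.
hwe_enumerate_logp <- function(a, cap = 1e5) {
  k <- length(a)
  N <- sum(a) / 2
  lconst <- hwe_log_const(N, a)
  acc <- new.env(parent = emptyenv())
  acc$v <- numeric(256)
  acc$n <- 0L
  acc$overflow <- FALSE
  emit <- function(h, sumlf) {
    if (acc$overflow) return(invisible())
    acc$n <- acc$n + 1L
    if (acc$n > cap) {
      acc$overflow <- TRUE
      return(invisible())
    }
    if (acc$n > length(acc$v)) acc$v <- c(acc$v, numeric(length(acc$v)))
    acc$v[acc$n] <- lconst + h * log(2) - sumlf
    invisible()
  }
  # rows of the (upper-triangular) genotype-count matrix are filled in order;
  # rem tracks unplaced copies of each allele
  distribute <- function(i, j, rem, left, h, sumlf) {
    if (acc$overflow) return(invisible())
    if (j == k) {
      if (left <= rem[k]) {
        rem[k] <- rem[k] - left
        rec(i + 1L, rem, h + left, sumlf + lfactorial(left))
      }
      return(invisible())
    }
    for (n in 0:min(left, rem[j])) {
      rem2 <- rem
      rem2[j] <- rem2[j] - n
      distribute(i, j + 1L, rem2, left - n, h + n, sumlf + lfactorial(n))
    }
    invisible()
  }
  rec <- function(i, rem, h, sumlf) {
    if (acc$overflow) return(invisible())
    if (i == k) {
      if (rem[k] %% 2L == 0L) emit(h, sumlf + lfactorial(rem[k] %/% 2L))
      return(invisible())
    }
    for (nii in 0:(rem[i] %/% 2L)) {
      distribute(i, i + 1L, rem, rem[i] - 2L * nii, h,
                 sumlf + lfactorial(nii))
    }
    invisible()
  }
  rec(1L, as.integer(a), 0L, 0)
  if (acc$overflow) return(NULL)
  acc$v[seq_len(acc$n)]
}

# observed configuration summary: het count and sum lfactorial(n_ij)
hwe_observed <- function(calls, allele_levels) {
  i <- match(calls$allele1, allele_levels)
  j <- match(calls$allele2, allele_levels)
  k <- length(allele_levels)
  code <- (pmin(i, j) - 1L) * k + pmax(i, j)
  tab <- tabulate(code, nbins = k * k)
  list(h = sum(i != j), sumlf = sum(lfactorial(tab)))
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Probability test of HWE conditional on the observed allele counts: the
#' p-value is the total probability, under the conditional (Levene)
#' distribution, of genotype configurations no more probable than the
#' observed one. Configurations are fully enumerated when their number does
#' not exceed `enum_cap`; otherwise the null distribution is sampled by
#' `reps` random pairings of the `2N` allele copies and the p-value is the
#' proportion of sampled configurations (the observed one included as a
#' draw) with probability at most the observed probability.
#'
#' @inheritParams allele_stats
#' @param reps Monte-Carlo replicates when enumeration is infeasible
#'   (default 1e5).
#' @param seed optional integer seed for the Monte-Carlo sampler.
#' @param enum_cap maximum number of configurations to enumerate (default
#'   1e5).
#' @return list with `p_value`, `method` (`"enumeration"`, `"monte_carlo"`
#'   or `"degenerate"`) and `reps` (`NA` unless Monte Carlo). A locus with
#'   fewer than 2 genotyped individuals or fewer than 2 alleles is
#'   degenerate: `p_value = 1`.
#' @export
hwe_test <- function(table, locus, reps = 1e5, seed = NULL, enum_cap = 1e5) {
  calls <- locus_calls(table, locus)
  calls <- calls[!is.na(calls$allele1), , drop = FALSE]
  alleles <- sort(unique(c(calls$allele1, calls$allele2)))
  N <- nrow(calls)
  k <- length(alleles)
  if (N < 2 || k < 2) {
    return(list(p_value = 1.0, method = "degenerate", reps = NA_integer_))
  }
  a <- as.integer(table(factor(c(calls$allele1, calls$allele2),
                               levels = alleles)))
  lconst <- hwe_log_const(N, a)
  obs <- hwe_observed(calls, alleles)
  logp_obs <- lconst + obs$h * log(2) - obs$sumlf
  tol <- 1e-9 * abs(logp_obs) + 1e-12

  logp_all <- hwe_enumerate_logp(a, cap = enum_cap)
  if (!is.null(logp_all)) {
    p <- sum(exp(logp_all[logp_all <= logp_obs + tol]))
    return(list(p_value = min(p, 1.0), method = "enumeration",
                reps = NA_integer_))
  }
  # Monte Carlo: shuffle the 2N allele copies and re-pair them
  if (!is.null(seed)) set.seed(seed)
  pool <- rep.int(seq_len(k), a)
  two_n <- 2L * N
  hits <- 0L
  for (r in seq_len(reps)) {
    perm <- pool[sample.int(two_n)]
    g1 <- perm[seq(1L, two_n, by = 2L)]
    g2 <- perm[seq(2L, two_n, by = 2L)]
    code <- (pmin(g1, g2) - 1L) * k + pmax(g1, g2)
    tab <- tabulate(code, nbins = k * k)
    logp <- lconst + sum(g1 != g2) * log(2) - sum(lfactorial(tab))
    if (logp <= logp_obs + tol) hits <- hits + 1L
  }
  list(p_value = (hits + 1) / (reps + 1), method = "monte_carlo",
       reps = as.integer(reps))
}

#' Null-allele frequency estimators
#'
#' Null alleles (alleles that fail to amplify) inflate apparent
#' homozygosity; their frequency can be estimated from the gap between
#' expected and observed heterozygosity. Two classical estimators:
#' Chakraborty's `r = (H_E - H_O) / (H_E + H_O)` and Brookfield's first
#' estimator `r = (H_E - H_O) / (1 + H_E)`.
#'
#' @param H_E,H_O expected and observed heterozygosity, both in `[0, 1]`.
#' @return list with `chakraborty` and `brookfield1` (negative raw values
#'   floored at 0) plus `chakraborty_raw` and `brookfield1_raw` (unfloored).
#'   `chakraborty` is `NA` when `H_E + H_O == 0` (no polymorphism signal).
#' @export
null_allele_estimates <- function(H_E, H_O) {
  stopifnot(H_E >= 0, H_E <= 1, H_O >= 0, H_O <= 1)
  chak_raw <- if (H_E + H_O == 0) NA_real_ else (H_E - H_O) / (H_E + H_O)
  brook_raw <- (H_E - H_O) / (1 + H_E)
  list(chakraborty = if (is.na(chak_raw)) NA_real_ else max(0, chak_raw),
       brookfield1 = max(0, brook_raw),
       chakraborty_raw = chak_raw,
       brookfield1_raw = brook_raw)
}

#' Per-locus summary and panel aggregates
#'
#' Computes, for every locus of a genotype table, the standard marker
#' characterization row — sample size, allele-size range, allele count,
#' observed and unbiased expected heterozygosity, exact HWE p-value and
#' null-allele estimates — plus the panel-level aggregates: mean `N_A`,
#' mean `H_E`, mean `H_O` and the number of loci consistent with HWE at
#' level `alpha`. Missing genotypes are excluded locus-wise (per-locus `N`
#' varies), never imputed.
#'
#' Alternatively accepts a pre-computed per-locus summary data.frame (with
#' columns `N_A`, `H_E`, `H_O`, `P_HWE`, as returned by [table1_fixture()])
#' and recomputes only the aggregates.
#'
#' @param x a [genotype_table] or a pre-computed per-locus summary
#'   data.frame.
#' @param alpha HWE significance level (default 0.05); a locus is "in HWE"
#'   when `p >= alpha`.
#' @param hwe_reps,seed,enum_cap passed to [hwe_test()].
#' @return an object of class `panel_summary`: list with `loci` (per-locus
#'   data.frame), `mean_NA`, `mean_HE`, `mean_HO`, `n_in_hwe`, `n_loci`,
#'   `alpha`. Means are over loci with defined values.
#' @export
summarize_panel <- function(x, alpha = 0.05, hwe_reps = 1e5, seed = NULL,
                            enum_cap = 1e5) {
  if (inherits(x, "genotype_table")) {
    loci_ids <- attr(x, "loci")
    if (length(loci_ids) == 0) stop("empty genotype table", call. = FALSE)
    rows <- lapply(loci_ids, function(l) {
      st <- allele_stats(x, l)
      ho <- observed_het(x, l)
      he <- unbiased_expected_het(st$freqs, st$N)
      hw <- hwe_test(x, l, reps = hwe_reps, seed = seed, enum_cap = enum_cap)
      nulls <- null_allele_estimates(min(he, 1), min(ho, 1))
      data.frame(locus = l, N = st$N,
                 size_min = st$size_range[1], size_max = st$size_range[2],
                 N_A = st$N_A, H_E = he, H_O = ho,
                 P_HWE = hw$p_value, hwe_method = hw$method,
                 null_chakraborty = nulls$chakraborty,
                 null_brookfield1 = nulls$brookfield1,
                 stringsAsFactors = FALSE)
    })
    loci <- do.call(rbind, rows)
  } else {
    loci <- as.data.frame(x)
    need <- c("N_A", "H_E", "H_O", "P_HWE")
    if (nrow(loci) == 0 || !all(need %in% names(loci))) {
      stop("need a genotype_table or a summary data.frame with columns ",
           paste(need, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(
    loci = loci,
    mean_NA = mean(loci$N_A, na.rm = TRUE),
    mean_HE = mean(loci$H_E, na.rm = TRUE),
    mean_HO = mean(loci$H_O, na.rm = TRUE),
    n_in_hwe = sum(loci$P_HWE >= alpha, na.rm = TRUE),
    n_loci = nrow(loci),
    alpha = alpha
  ), class = "panel_summary")
}

#' @export
print.panel_summary <- function(x, ...) {
  cat("<panel_summary>", x$n_loci, "loci\n")
  cat(sprintf("  mean N_A = %.1f, mean H_E = %.3f, mean H_O = %.3f\n",
              x$mean_NA, x$mean_HE, x$mean_HO))
  cat(sprintf("  %d loci in HWE at alpha = %g\n", x$n_in_hwe, x$alpha))
  invisible(x)
}

#' @export
summary.panel_summary <- function(object, ...) {
  print(object)
  invisible(object$loci)
}
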