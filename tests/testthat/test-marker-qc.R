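test_that("allele stats count copies and frequencies sum to one", {
  gt <- gt_from_pairs(c(120L, 120L), c(124L, 120L))
  st <- allele_stats(gt, "L1")
  expect_equal(st$N, 2)
  expect_equal(st$freqs, c(`120` = 0.75, `124` = 0.25))
  expect_equal(st$N_A, 2)
  expect_equal(st$size_range, c(120, 124))

  gt <- gt_from_pairs(100L, 100L)
  st <- allele_stats(gt, "L1")
  expect_equal(st$N_A, 1)
  expect_equal(unname(st$freqs), 1.0)

  # all-missing locus errors with the locus name
  gt <- genotype_table(data.frame(sample = "s1", locus = "Lbad",
                                  allele1 = NA_integer_,
                                  allele2 = NA_integer_))
  expect_error(allele_stats(gt, "Lbad"), "Lbad")

  # property: frequencies always sum to 1
  set.seed(21)
  for (rep in 1:100) {
    n <- sample(2:30, 1)
    sizes <- sample(seq(100L, 140L, 4L), 4)
    gt <- gt_from_pairs(sample(sizes, n, TRUE), sample(sizes, n, TRUE))
    expect_equal(sum(allele_stats(gt, "L1")$freqs), 1)
  }
})

test_that("observed heterozygosity is the heterozygote fraction", {
  a1 <- c(rep(100L, 14), rep(100L, 10))
  a2 <- c(rep(100L, 14), rep(104L, 10))
  expect_equal(observed_het(gt_from_pairs(a1, a2), "L1"), 10 / 24)
  expect_equal(observed_het(gt_from_pairs(c(100L, 104L), c(100L, 104L)), "L1"), 0)
  expect_equal(observed_het(gt_from_pairs(c(100L, 100L), c(104L, 108L)), "L1"), 1)
})

test_that("unbiased expected heterozygosity applies Nei's correction", {
  expect_equal(unbiased_expected_het(c(0.5, 0.5), 24), (48 / 47) * 0.5)
  expect_equal(unbiased_expected_het(1.0, 10), 0)
  expect_warning(h <- unbiased_expected_het(c(0.5, 0.5), 1), "N = 1")
  expect_equal(h, 0.5)
  expect_equal(unbiased_expected_het(c(0.25, 0.75), 10, correct = FALSE),
               1 - 0.25^2 - 0.75^2)
  # algebraic oracle: pairwise-product form
  set.seed(33)
  for (rep in 1:200) {
    k <- sample(2:8, 1)
    p <- runif(k); p <- p / sum(p)
    N <- sample(2:100, 1)
    expect_equal(unbiased_expected_het(p, N), oracle_expected_het(p, N))
  }
  # invariant to allele label permutation
  p <- c(`100` = 0.2, `104` = 0.3, `108` = 0.5)
  expect_equal(unbiased_expected_het(p, 12),
               unbiased_expected_het(rev(p), 12))
})

test_that("exact HWE test reproduces hand-enumerated probabilities", {
  # two homozygotes AA, BB: configs {AA,BB} (prob 1/3) and {AB,AB} (2/3)
  gt <- gt_from_pairs(c(100L, 104L), c(100L, 104L))
  res <- hwe_test(gt, "L1")
  expect_equal(res$p_value, 1 / 3)
  expect_equal(res$method, "enumeration")
  # the double heterozygote is the most probable config: p = 1
  gt <- gt_from_pairs(c(100L, 100L), c(104L, 104L))
  expect_equal(hwe_test(gt, "L1")$p_value, 1)
  # degenerate: single allele
  gt <- gt_from_pairs(c(100L, 100L, 100L), c(100L, 100L, 100L))
  res <- hwe_test(gt, "L1")
  expect_equal(res$p_value, 1)
  expect_equal(res$method, "degenerate")
})

test_that("enumerated conditional distribution is a proper distribution", {
  set.seed(55)
  for (rep in 1:20) {
    n <- sample(3:10, 1)
    sizes <- sample(seq(100L, 112L, 4L), sample(2:4, 1))
    gt <- gt_from_pairs(sample(sizes, n, TRUE), sample(sizes, n, TRUE))
    st <- allele_stats(gt, "L1")
    if (st$N_A < 2) next
    logs <- msatdev:::hwe_enumerate_logp(
      as.integer(round(st$freqs * 2 * st$N)), cap = 1e5)
    expect_equal(sum(exp(logs)), 1, tolerance = 1e-9)
  }
})

test_that("enumeration and Monte Carlo agree on small instances", {
  set.seed(66)
  for (rep in 1:12) {
    n <- sample(4:8, 1)
    sizes <- sample(seq(100L, 108L, 4L), sample(2:3, 1))
    gt <- gt_from_pairs(sample(sizes, n, TRUE), sample(sizes, n, TRUE))
    if (allele_stats(gt, "L1")$N_A < 2) next
    exact <- hwe_test(gt, "L1")
    expect_equal(exact$method, "enumeration")
    reps <- 20000
    mc <- hwe_test(gt, "L1", reps = reps, seed = 100 + rep, enum_cap = 1)
    expect_equal(mc$method, "monte_carlo")
    se <- sqrt(exact$p_value * (1 - exact$p_value) / reps)
    expect_lt(abs(mc$p_value - exact$p_value), 3 * se + 2 / reps)
  }
})

test_that("null-allele estimators follow the heterozygote-deficit formulas", {
  est <- null_allele_estimates(0.6, 0.4)
  expect_equal(est$chakraborty, 0.2)          # (0.6-0.4)/(0.6+0.4)
  expect_equal(est$brookfield1, 0.125)        # (0.6-0.4)/(1+0.6)
  est <- null_allele_estimates(0.5, 0.5)
  expect_equal(est$chakraborty, 0)
  expect_equal(est$brookfield1, 0)
  # excess heterozygosity floors at zero but keeps the raw value
  est <- null_allele_estimates(0.4, 0.6)
  expect_equal(est$chakraborty, 0)
  expect_equal(est$chakraborty_raw, -0.2)
  expect_equal(est$brookfield1, 0)
  expect_lt(est$brookfield1_raw, 0)
  expect_true(is.na(null_allele_estimates(0, 0)$chakraborty))
})

test_that("panel summary aggregates per-locus statistics", {
  gt <- make_genotypes(20, list(
    L1 = list(freqs = c(`100` = 0.5, `104` = 0.5)),
    L2 = list(freqs = c(`200` = 0.25, `204` = 0.25, `208` = 0.5))
  ), seed = 12)
  ps <- summarize_panel(gt, seed = 12)
  expect_s3_class(ps, "panel_summary")
  expect_equal(ps$n_loci, 2)
  expect_equal(ps$mean_NA, mean(ps$loci$N_A))
  expect_equal(ps$mean_HE, mean(ps$loci$H_E))
  expect_equal(ps$mean_HO, mean(ps$loci$H_O))
  expect_true(all(ps$loci$H_E >= 0 & ps$loci$H_E <= 1))
  expect_true(all(ps$loci$P_HWE >= 0 & ps$loci$P_HWE <= 1))

  # single locus: means equal that locus's values
  one <- summarize_panel(make_genotypes(10, list(
    L1 = list(freqs = c(`100` = 0.5, `104` = 0.5))), seed = 3))
  expect_equal(one$mean_HE, one$loci$H_E[1])

  # alpha = 1 boundary: only loci with p exactly 1 count as in HWE
  expect_equal(summarize_panel(ps$loci, alpha = 1.0)$n_in_hwe,
               sum(ps$loci$P_HWE == 1))

  expect_error(summarize_panel(data.frame()), "genotype_table")
})

test_that("H_E is invariant to sample order", {
  set.seed(14)
  a1 <- sample(seq(100L, 116L, 4L), 30, TRUE)
  a2 <- sample(seq(100L, 116L, 4L), 30, TRUE)
  gt1 <- gt_from_pairs(a1, a2)
  perm <- sample(30)
  gt2 <- gt_from_pairs(a1[perm], a2[perm])
  expect_equal(observed_het(gt1, "L1"), observed_het(gt2, "L1"))
  s1 <- allele_stats(gt1, "L1"); s2 <- allele_stats(gt2, "L1")
  expect_equal(unbiased_expected_het(s1$freqs, s1$N),
               unbiased_expected_het(s2$freqs, s2$N))
})
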