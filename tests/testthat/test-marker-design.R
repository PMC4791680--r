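make_locus <- function(scaffold, start, end, motif = "AAAG") {
  data.frame(scaffold = scaffold, start = start, end = end, motif = motif,
             canonical = canonical_motif(motif), period = nchar(motif),
             n_repeats = (end - start) %/% nchar(motif),
             stringsAsFactors = FALSE)
}

test_that("flank extraction clips at scaffold ends and records it", {
  set.seed(2)
  seq <- random_dna(10000)
  # centered locus: both flanks full length
  cand <- extract_flanks(seq, make_locus("s", 5000, 5040), flank_len = 200)
  expect_equal(nchar(cand$left_flank), 200)
  expect_equal(nchar(cand$right_flank), 200)
  expect_true(cand$designable)

  # locus near the start: left flank clipped but still >= 24 bp
  cand <- extract_flanks(seq, make_locus("s", 100, 140), flank_len = 200)
  expect_equal(nchar(cand$left_flank), 100)
  expect_true(cand$left_clipped)
  expect_true(cand$designable)
  expect_match(cand$reason, "clipped")

  # locus at the very start: no room for a left primer
  cand <- extract_flanks(seq, make_locus("s", 0, 40), flank_len = 200)
  expect_equal(nchar(cand$left_flank), 0)
  expect_false(cand$designable)
  expect_match(cand$reason, "left flank too short")

  expect_error(extract_flanks(seq, make_locus("s", 9990, 10030)), "outside")
})

test_that("flank + repeat + flank reassembles a contiguous scaffold slice", {
  set.seed(8)
  seq <- random_dna(3000)
  locus <- make_locus("s", 1200, 1248, "ACTC")
  # force the repeat into the scaffold so the slice identity is exact
  substr(seq, 1201, 1248) <- strrep("ACTC", 12)
  cand <- extract_flanks(seq, locus, flank_len = 150)
  slice <- paste0(cand$left_flank, substr(seq, 1201, 1248), cand$right_flank)
  expect_identical(slice, substr(seq, 1051, 1398))
})

test_that("designability constraints: product size, N runs, N fraction", {
  params <- primer_params()
  clean <- strrep("ACGT", 50)  # 200 bp flank

  base <- make_locus("s", 200, 260)
  cand <- cbind(base, data.frame(
    left_flank = clean, right_flank = clean, left_clipped = FALSE,
    right_clipped = FALSE, designable = TRUE, reason = "", tag = "none",
    expected_product_min = NA_integer_, expected_product_max = NA_integer_,
    stringsAsFactors = FALSE))
  out <- designability_check(cand, params)
  expect_true(out$designable)   # 60 + 2*20 <= 450
  expect_equal(out$expected_product_min, 100)

  long <- cand
  long$end <- long$start + 420  # 420 + 40 > 450
  out <- designability_check(long, params)
  expect_false(out$designable)
  expect_match(out$reason, "product cap")

  # monotone: raising the cap never revokes designability
  relaxed <- designability_check(long, primer_params(max_product = 1000))
  expect_true(relaxed$designable)

  dirty <- cand
  dirty$left_flank <- paste0(strrep("AN", 50), strrep("ACGT", 25))  # 50% N half
  out <- designability_check(dirty, params)
  expect_false(out$designable)
  expect_match(out$reason, "ambiguity")

  chopped <- cand
  chopped$right_flank <- paste(rep(strrep("ACGTACGTACGTACGTACGT", 1), 9),
                               collapse = "N")  # 20-bp islands only
  out <- designability_check(chopped, params)
  expect_false(out$designable)
  expect_match(out$reason, "contiguous")
})

test_that("universal tags prepend exactly and unknown tags error", {
  expect_identical(add_tag("ACGTACGTACGTACGTACGT", "M13R"),
                   "GGAAACAGCTATGACCATACGTACGTACGTACGTACGT")
  tagged <- add_tag("A", "CAG")
  expect_identical(tagged, "CAGTCGGGCGTCATCAA")
  expect_equal(nchar(tagged), 17)
  expect_error(add_tag("ACGT", "M13F"), "unknown tag")
  # tagged length is primer length plus tag length, exactly
  for (tag in names(tag_sequences)) {
    p <- random_dna(22)
    expect_equal(nchar(add_tag(p, tag)), 22 + nchar(tag_sequences[[tag]]))
  }
})

test_that("panel selection is stratified, seeded and respects exclusions", {
  set.seed(30)
  groups <- rep(sprintf("chr%d", 1:19), each = 6)
  cand <- do.call(rbind, lapply(seq_along(groups), function(i) {
    c <- make_locus("s", i * 1000, i * 1000 + 40)
    c$left_flank <- strrep("ACGT", 50); c$right_flank <- strrep("ACGT", 50)
    c$left_clipped <- FALSE; c$right_clipped <- FALSE
    c$designable <- TRUE; c$reason <- ""; c$tag <- "none"
    c$expected_product_min <- 100L; c$expected_product_max <- 450L
    c
  }))
  panel <- select_panel(cand, groups, 2, 5,
                        exclude_groups = c("chr7", "chrX", "chrY"), seed = 9)
  expect_false(any(panel$group == "chr7"))
  per_group <- table(panel$group)
  expect_true(all(per_group >= 2 & per_group <= 5))
  expect_equal(length(per_group), 18)  # 19 groups minus chr7
  expect_gte(nrow(panel), 2 * 18)
  expect_lte(nrow(panel), 5 * 18)

  panel2 <- select_panel(cand, groups, 2, 5,
                         exclude_groups = c("chr7", "chrX", "chrY"), seed = 9)
  expect_identical(panel, panel2)

  # under-filled groups contribute everything, with a warning
  few <- cand[1:1, , drop = FALSE]
  expect_warning(out <- select_panel(few, "chr1", 2, 5, seed = 1),
                 "fewer than k_min")
  expect_equal(nrow(out), 1)

  # non-designable candidates never enter the panel
  cand$designable[groups == "chr1"] <- FALSE
  expect_warning(panel3 <- select_panel(cand, groups, 2, 5, seed = 9),
                 "chr1")
  expect_false(any(panel3$group == "chr1"))
})
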