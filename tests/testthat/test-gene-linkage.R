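locus_row <- function(start, end, scaffold = "sc1") {
  data.frame(scaffold = scaffold, start = start, end = end,
             stringsAsFactors = FALSE)
}

ann_one <- function(starts, ends, scaffold = "sc1",
                    symbols = sprintf("Sym%d", seq_along(starts))) {
  genes <- data.frame(gene_id = sprintf("g%d", seq_along(starts)),
                      symbol = symbols, scaffold = scaffold,
                      start = starts, end = ends, strand = "+",
                      stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = genes$gene_id, scaffold = scaffold,
                      start = starts, end = ends, kind = "exon",
                      stringsAsFactors = FALSE)
  gene_annotation(genes, exons)
}

test_that("nearest-feature distance uses half-open gap arithmetic", {
  ann <- ann_one(500, 900)
  expect_equal(nearest_feature_distance(locus_row(1000, 1040), ann), 100)
  ann <- ann_one(1020, 1100)
  expect_equal(nearest_feature_distance(locus_row(1000, 1040), ann), 0)
  # no feature on this scaffold
  expect_true(is.na(nearest_feature_distance(locus_row(0, 10, "other"), ann)))
})

test_that("nearest distance matches a linear-scan oracle on random inputs", {
  set.seed(404)
  for (rep in 1:300) {
    n <- sample(1:40, 1)
    ann <- random_annotation(n)
    l <- locus_row(s <- sample.int(1e6 - 100, 1), s + sample.int(80, 1))
    got <- nearest_feature_distance(l, ann)
    want <- oracle_nearest(l$start, l$end, ann$exons$start, ann$exons$end)
    expect_equal(got, want)
  }
})

test_that("windowed gene query matches a linear scan and signs distances", {
  # constructed cases
  ann <- ann_one(c(150000, 400000), c(154000, 404000))
  l <- locus_row(200000, 200040)
  w <- genes_in_window(l, ann, half_width = 1e5)
  expect_equal(w$symbol, "Sym1")        # 50 kbp upstream gene only
  expect_equal(w$distance, -46000)      # gap from gene end 154000 to 200000
  # gene straddling the window edge is included
  ann <- ann_one(99000, 101000)
  expect_equal(nrow(genes_in_window(locus_row(200000, 200040), ann, 1e5)), 1)
  # gene fully outside
  ann <- ann_one(0, 90000)
  expect_equal(nrow(genes_in_window(locus_row(200000, 200040), ann, 1e5)), 0)

  # random equivalence with the brute-force scan
  set.seed(505)
  for (rep in 1:200) {
    ann <- random_annotation(sample(1:50, 1))
    l <- locus_row(s <- sample.int(9e5, 1), s + 40)
    half <- sample(c(0, 1000, 50000, 100000), 1)
    got <- genes_in_window(l, ann, half_width = half)
    want <- oracle_in_window(l$start, l$end, half,
                             ann$genes$start, ann$genes$end)
    expect_setequal(got$gene_id, ann$genes$gene_id[want])
    # sorted by |distance|
    expect_false(is.unsorted(abs(got$distance)))
    # overlap means distance zero; distances never exceed the half-width
    over <- got$start < l$end & got$end > l$start
    expect_true(all(got$distance[over] == 0))
    expect_true(all(abs(got$distance) <= half | over))
  }
})

test_that("predicted/uncharacterized symbol classes are excluded", {
  expect_equal(
    exclude_predicted(c("Gm123", "Nrxn1", "LOC456", "Mir21", "2410004B18Rik")),
    "Nrxn1")
  expect_equal(exclude_predicted("Gmppa"), "Gmppa")  # Gm not followed by digit
  expect_equal(exclude_predicted(character(0)), character(0))
  expect_equal(exclude_predicted(c("Mirabilis", "LOCKE")),
               c("Mirabilis", "LOCKE"))
})

test_that("dual-evidence filter intersects annotation and homology", {
  expect_setequal(dual_evidence_filter(c("A1", "B1", "C1"), c("B1", "C1", "D1")),
                  c("B1", "C1"))
  # predicted genes are removed before intersection
  expect_equal(dual_evidence_filter(c("Gm123", "Bmpr2"), c("Gm123", "Bmpr2")),
               "Bmpr2")
  expect_equal(dual_evidence_filter(c("A1", "B1"), character(0)), character(0))
  # case/isoform-insensitive matching
  expect_equal(dual_evidence_filter("Nrxn1", "NRXN1-1"), "Nrxn1")
  # output contained in both inputs (after normalization), random property
  set.seed(9)
  for (rep in 1:50) {
    win <- sample(c("Aa1", "Bb1", "Cc1", "Gm99", "Dd1"), sample(0:5, 1))
    hit <- sample(c("AA1", "BB1", "EE1"), sample(0:3, 1))
    out <- dual_evidence_filter(win, hit)
    expect_true(all(out %in% win))
    expect_true(all(normalize_symbol(out) %in% normalize_symbol(hit)))
  }
})

test_that("linkage summary histograms count loci and sum to one", {
  reports <- data.frame(
    locus_id = sprintf("L%d", 1:10),
    nearest_exon_distance = c(rep(50000, 7), 150000, 250000, NA),
    n_genes_window = c(0, 0, 1, 1, 1, 1, 1, 2, 2, 3),
    linked_genes = "",
    n_linked = c(0, 0, 1, 1, 1, 1, 1, 2, 2, 3),
    stringsAsFactors = FALSE)
  s <- linkage_summary(reports)
  # 7 of 9 categorized loci are < 100 kbp from the nearest exon
  lt100 <- sum(s$distance$count[s$distance$bin_end <= 1e5])
  expect_equal(lt100 / sum(s$distance$count), 7 / 9)
  expect_equal(s$no_feature, 1)
  expect_equal(sum(s$distance$fraction), 1, tolerance = 1e-12)
  expect_equal(s$gene_count$fraction, c(0.2, 0.5, 0.2, 0.1))
  expect_equal(sum(s$gene_count$fraction), 1, tolerance = 1e-12)

  empty <- linkage_summary(reports[0, , drop = FALSE])
  expect_equal(nrow(empty$distance), 0)
  expect_equal(nrow(empty$gene_count), 0)
})

test_that("linkage_report wires window, filter and distances together", {
  ann <- ann_one(c(10000, 60000, 300000), c(14000, 64000, 304000),
                 symbols = c("Bmpr2", "Gm123", "Akap6"))
  loci <- data.frame(scaffold = "sc1", start = 50000, end = 50040,
                     locus_id = "L1", stringsAsFactors = FALSE)
  hits <- data.frame(query_id = c("L1", "L1"),
                     gene_symbol = c("Bmpr2", "Gm123"),
                     stringsAsFactors = FALSE)
  rep <- linkage_report(loci, ann, hits, half_width = 1e5)
  expect_equal(rep$nearest_exon_distance, 9960)   # gap to exon [60000,64000)
  expect_equal(rep$n_genes_window, 1)             # Gm123 excluded, Akap6 too far
  expect_equal(rep$linked_genes, "Bmpr2")
  expect_equal(rep$n_linked, 1)
})
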