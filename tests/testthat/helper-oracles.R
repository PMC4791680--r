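# Independent brute-force oracles. These deliberately share no code with the
# package: character-by-character loops and linear scans only.

# all maximal perfect tandem runs of `period`-length units with >= min_repeats
# whole copies, leftmost-anchored, homopolymer units excluded
oracle_repeats <- function(seq, period, min_repeats) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  valid <- ch %in% c("A", "C", "G", "T")
  rows <- list()
  i <- 1
  while (i + period * min_repeats - 1 <= n) {
    if (all(valid[i:(i + period - 1)])) {
      unit <- ch[i:(i + period - 1)]
      m <- 1
      while (i + (m + 1) * period - 1 <= n &&
             all(ch[(i + m * period):(i + (m + 1) * period - 1)] == unit) &&
             all(valid[(i + m * period):(i + (m + 1) * period - 1)])) {
        m <- m + 1
      }
      leftmost <- i == 1 || !valid[i - 1] || ch[i - 1] != ch[i - 1 + period]
      if (m >= min_repeats && leftmost && length(unique(unit)) > 1) {
        rows[[length(rows) + 1]] <- data.frame(
          start = i - 1, end = i - 1 + m * period,
          motif = paste(unit, collapse = ""), stringsAsFactors = FALSE)
      }
    }
    i <- i + 1
  }
  if (length(rows)) {
    out <- do.call(rbind, rows)
    out[order(out$start, out$end), , drop = FALSE]
  } else {
    data.frame(start = integer(0), end = integer(0), motif = character(0),
               stringsAsFactors = FALSE)
  }
}

# random DNA string; a restricted alphabet raises tandem-repeat density
random_dna <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# linear-scan nearest distance between half-open intervals (0 on overlap)
oracle_nearest <- function(l_start, l_end, f_start, f_end) {
  if (length(f_start) == 0) return(NA_integer_)
  gaps <- vapply(seq_along(f_start), function(i) {
    if (l_start < f_end[i] && f_start[i] < l_end) 0
    else if (f_start[i] >= l_end) f_start[i] - l_end
    else l_start - f_end[i]
  }, numeric(1))
  min(gaps)
}

# linear-scan window membership: gene intervals intersecting the window
oracle_in_window <- function(l_start, l_end, half, g_start, g_end) {
  w_start <- max(0, l_start - half)
  w_end <- l_end + half
  which(g_end > w_start & g_start < w_end)
}

# independent minimal GenePop parser: returns data.frame(sample, locus,
# size1, size2) with sizes decoded through the sidecar allele map
independent_genepop <- function(path) {
  lines <- readLines(path)
  pop <- which(tolower(trimws(lines)) == "pop")[1]
  loci <- trimws(lines[2:(pop - 1)])
  map <- utils::read.csv(paste0(path, ".allele_map.csv"),
                         colClasses = c("character", "integer", "character"))
  rows <- list()
  for (ln in lines[(pop + 1):length(lines)]) {
    if (!nzchar(trimws(ln))) next
    sample_id <- trimws(sub(",.*$", "", ln))
    codes <- strsplit(trimws(sub("^[^,]*,", "", ln)), "\\s+")[[1]]
    for (i in seq_along(loci)) {
      dec <- function(c3) {
        if (c3 == "000") return(NA_integer_)
        map$size[map$locus == loci[i] & map$code == c3]
      }
      s1 <- dec(substr(codes[i], 1, 3))
      s2 <- dec(substr(codes[i], 4, 6))
      rows[[length(rows) + 1]] <- data.frame(
        sample = sample_id, locus = loci[i],
        size1 = min(s1, s2), size2 = max(s1, s2), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# expected heterozygosity by the pairwise-sum definition
oracle_expected_het <- function(p, N) {
  s <- 0
  for (i in seq_along(p)) {
    for (j in seq_along(p)) {
      if (i != j) s <- s + p[i] * p[j]
    }
  }
  s * 2 * N / (2 * N - 1)
}

# small genotype table straight from allele vectors
gt_from_pairs <- function(a1, a2, locus = "L1") {
  genotype_table(data.frame(
    sample = sprintf("s%d", seq_along(a1)), locus = locus,
    allele1 = a1, allele2 = a2, stringsAsFactors = FALSE))
}

# random annotation on one scaffold for interval-oracle tests
random_annotation <- function(n_genes, scaffold = "sc1", span = 1e6) {
  start <- sort(sample.int(span - 2000L, n_genes))
  end <- start + sample.int(1500L, n_genes, replace = TRUE)
  genes <- data.frame(
    gene_id = sprintf("g%d", seq_len(n_genes)),
    symbol = sprintf("Sym%d", seq_len(n_genes)),
    scaffold = scaffold, start = start, end = end, strand = "+",
    stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = genes$gene_id, scaffold = scaffold,
                      start = start, end = end, kind = "exon",
                      stringsAsFactors = FALSE)
  gene_annotation(genes, exons)
}
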