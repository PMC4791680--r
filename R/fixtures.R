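# Seeded synthetic-data generators. Every generator records its ground truth
# so detector output can be checked exactly, and is deterministic for a fixed
# seed.

#' Generate synthetic scaffolds with planted repeats and gap runs
#'
#' Emulates reference-mapped consensus scaffolds: i.i.d. uniform ACGT
#' background with planted `N` runs (mapping gaps) and planted perfect
#' tandem repeats. The background is rejection-checked so that, at the
#' stated screening rule (`period`, `min_repeats`), the detector finds
#' exactly the planted loci — the returned truth is exhaustive.
#'
#' @param n_scaffolds number of scaffolds.
#' @param length scaffold length in bp (recycled across scaffolds).
#' @param planted_repeats data.frame with columns `scaffold` (index in
#'   `1..n_scaffolds`), `motif`, `n_repeats`, `position` (0-based start).
#'   Planted repeats must be non-overlapping and separated by at least one
#'   repeat unit of non-repeat sequence.
#' @param gap_runs optional data.frame with columns `scaffold`, `start`,
#'   `length` describing planted `N` runs.
#' @param seed integer seed.
#' @param period,min_repeats the screening rule the truth is exhaustive for
#'   (defaults 4 and 8).
#' @param max_tries background regeneration attempts before giving up
#'   (default 25).
#' @return list with `sequences` (named character vector,
#'   `scaffold_1 ...`), and `truth` (data.frame `scaffold`, `start`, `end`,
#'   `name` = motif, `n_repeats`), suitable for [write_fasta()] and
#'   [write_bed()].
#' @export
make_scaffolds <- function(n_scaffolds = 1L, length = 10000L,
                           planted_repeats = NULL, gap_runs = NULL,
                           seed = NULL, period = 4L, min_repeats = 8L,
                           max_tries = 25L) {
  if (!is.null(seed)) set.seed(seed)
  lens <- rep_len(as.integer(length), n_scaffolds)
  ids <- paste0("scaffold_", seq_len(n_scaffolds))
  pr <- if (is.null(planted_repeats)) {
    data.frame(scaffold = integer(0), motif = character(0),
               n_repeats = integer(0), position = integer(0))
  } else as.data.frame(planted_repeats, stringsAsFactors = FALSE)
  gr <- if (is.null(gap_runs)) {
    data.frame(scaffold = integer(0), start = integer(0), length = integer(0))
  } else as.data.frame(gap_runs, stringsAsFactors = FALSE)

  # feasibility: bounds, non-overlap, separation >= one unit
  for (s in seq_len(n_scaffolds)) {
    p <- pr[pr$scaffold == s, , drop = FALSE]
    if (nrow(p) == 0) next
    p$len <- nchar(p$motif) * p$n_repeats
    if (any(p$position < 0 | p$position + p$len > lens[s])) {
      stop("planted repeat outside scaffold ", s, call. = FALSE)
    }
    p <- p[order(p$position), , drop = FALSE]
    if (nrow(p) > 1) {
      gap <- p$position[-1] - (p$position[-nrow(p)] + p$len[-nrow(p)])
      if (any(gap < nchar(p$motif[-nrow(p)]))) {
        stop("planted repeats on scaffold ", s,
             " overlap or are separated by less than one unit", call. = FALSE)
      }
    }
  }

  truth <- data.frame(scaffold = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      n_repeats = integer(0), stringsAsFactors = FALSE)
  sequences <- character(n_scaffolds)
  names(sequences) <- ids
  for (s in seq_len(n_scaffolds)) {
    p <- pr[pr$scaffold == s, , drop = FALSE]
    g <- gr[gr$scaffold == s, , drop = FALSE]
    t_s <- data.frame(
      scaffold = rep(ids[s], nrow(p)),
      start = as.integer(p$position),
      end = as.integer(p$position + nchar(p$motif) * p$n_repeats),
      name = p$motif,
      n_repeats = as.integer(p$n_repeats),
      stringsAsFactors = FALSE
    )
    t_s <- t_s[order(t_s$start), , drop = FALSE]
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      chars <- sample(DNA_BASES, lens[s], replace = TRUE)
      for (j in seq_len(nrow(g))) {
        chars[(g$start[j] + 1):(g$start[j] + g$length[j])] <- "N"
      }
      for (j in seq_len(nrow(p))) {
        unit <- strsplit(p$motif[j], "", fixed = TRUE)[[1]]
        ins <- rep(unit, p$n_repeats[j])
        chars[(p$position[j] + 1):(p$position[j] + length(ins))] <- ins
      }
      seq_s <- paste(chars, collapse = "")
      found <- find_perfect_repeats(seq_s, period = period,
                                    min_repeats = min_repeats,
                                    scaffold_id = ids[s])
      same <- nrow(found) == nrow(t_s) &&
        (nrow(found) == 0 ||
           (all(found$start == t_s$start) && all(found$end == t_s$end) &&
              all(found$motif == t_s$name)))
      if (same) {
        sequences[s] <- seq_s
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("could not generate scaffold ", s, " matching its planted truth in ",
           max_tries, " attempts", call. = FALSE)
    }
    truth <- rbind(truth, t_s)
  }
  rownames(truth) <- NULL
  list(sequences = sequences, truth = truth)
}

# small pool of realistic gene symbols for synthetic annotation
SYMBOL_POOL <- c("Nrxn1", "Bmpr2", "Akap6", "Malt1", "Cep70", "Zfp706",
                 "Ubr5", "Rmdn2", "Meiob", "Kcnma1", "Tmem246", "Ccdc130",
                 "Olfr904", "Tmtc2", "Fam181a", "Mphosph6", "Dner", "Pum2",
                 "Slc8a1", "Vwc2l", "Ccbl2", "Nxph1")

predicted_symbol <- function(i) {
  switch((i %% 4L) + 1L,
         paste0("Gm", 1000L + i),
         paste0("LOC", 100000L + i),
         paste0("Mir", 100L + i),
         paste0(2410000L + i, "B18Rik"))
}

#' Generate a synthetic gene annotation
#'
#' Places non-overlapping genes with exon children on the given scaffolds; a
#' `predicted_fraction` of genes receive predicted/uncharacterized-class
#' symbols (`Gm#`, `LOC#`, `Mir#`, `...Rik`), the rest realistic symbols.
#'
#' @param scaffold_lengths named integer vector (scaffold id -> length in
#'   bp), e.g. `nchar(fixture$sequences)`.
#' @param n_genes genes per scaffold.
#' @param exons_per_gene exon children per gene (default 3).
#' @param predicted_fraction fraction of genes given predicted-class symbols
#'   (default 0).
#' @param gene_length gene span in bp (default 4000).
#' @param min_gap minimum intergenic gap in bp (default 500).
#' @param seed integer seed.
#' @return a [gene_annotation]; its `genes` slot is the symbol/coordinate
#'   truth table.
#' @export
make_annotation <- function(scaffold_lengths, n_genes = 10L,
                            exons_per_gene = 3L, predicted_fraction = 0,
                            gene_length = 4000L, min_gap = 500L, seed = NULL) {
  stopifnot(!is.null(names(scaffold_lengths)),
            predicted_fraction >= 0, predicted_fraction <= 1,
            exons_per_gene >= 1)
  if (!is.null(seed)) set.seed(seed)
  pitch <- gene_length + min_gap
  genes_list <- list()
  exons_list <- list()
  idx <- 0L
  for (sc in names(scaffold_lengths)) {
    slots <- scaffold_lengths[[sc]] %/% pitch
    if (slots < n_genes) {
      stop("cannot pack ", n_genes, " genes of ", gene_length, " bp (+",
           min_gap, " gap) into scaffold ", sc, call. = FALSE)
    }
    at <- sort(sample.int(slots, n_genes) - 1L)
    for (j in seq_len(n_genes)) {
      idx <- idx + 1L
      start <- at[j] * pitch
      end <- start + gene_length
      gid <- paste0("gene", idx)
      genes_list[[idx]] <- data.frame(
        gene_id = gid, symbol = NA_character_, scaffold = sc,
        start = start, end = end,
        strand = sample(c("+", "-"), 1L), stringsAsFactors = FALSE
      )
      # exons: alternate exon/intron chunks across the gene span
      chunk <- gene_length %/% (2L * exons_per_gene - 1L)
      ex_start <- start + (seq_len(exons_per_gene) - 1L) * 2L * chunk
      ex_end <- pmin(ex_start + chunk, end)
      exons_list[[idx]] <- data.frame(
        gene_id = gid, scaffold = sc, start = ex_start, end = ex_end,
        kind = "exon", stringsAsFactors = FALSE
      )
    }
  }
  genes <- do.call(rbind, genes_list)
  n_pred <- round(predicted_fraction * nrow(genes))
  pred_rows <- if (n_pred > 0) sample.int(nrow(genes), n_pred) else integer(0)
  symbols <- rep(SYMBOL_POOL, length.out = nrow(genes))
  dup <- duplicated(symbols)
  symbols[dup] <- paste0(symbols[dup], seq_len(sum(dup)))
  symbols[pred_rows] <- vapply(pred_rows, predicted_symbol, character(1))
  genes$symbol <- symbols
  gene_annotation(genes, do.call(rbind, exons_list))
}

#' Simulate a genotype panel under Hardy-Weinberg with optional null alleles
#'
#' Draws genotypes at Hardy-Weinberg proportions from an allele pool that may
#' include a null (non-amplifying) allele: visible allele frequencies are
#' scaled by `1 - null_freq`. Null homozygotes become missing calls; null
#' heterozygotes appear as visible homozygotes. Additional missingness is
#' applied at `missing_rate`.
#'
#' @param n_samples individuals in the panel (default 24).
#' @param loci_specs named list; each element is a list with `freqs` (named
#'   numeric vector, allele size -> frequency, summing to 1), and optional
#'   `null_freq` (default 0, must be `< 1`) and `missing_rate` (default 0).
#' @param seed integer seed.
#' @return a [genotype_table]; the specs are attached as attribute `"truth"`.
#' @export
make_genotypes <- function(n_samples = 24L, loci_specs, seed = NULL) {
  stopifnot(length(loci_specs) >= 1, !is.null(names(loci_specs)))
  if (!is.null(seed)) set.seed(seed)
  samples <- sprintf("S%02d", seq_len(n_samples))
  rows <- list()
  for (l in names(loci_specs)) {
    spec <- loci_specs[[l]]
    freqs <- spec$freqs
    null_freq <- spec$null_freq %||% 0
    missing_rate <- spec$missing_rate %||% 0
    stopifnot(abs(sum(freqs) - 1) < 1e-8, null_freq >= 0, null_freq < 1,
              missing_rate >= 0, missing_rate <= 1)
    sizes <- as.integer(names(freqs))
    # allele 0 stands for the null allele
    pool <- c(sizes, 0L)
    probs <- c(as.numeric(freqs) * (1 - null_freq), null_freq)
    a1 <- pool[sample.int(length(pool), n_samples, replace = TRUE, prob = probs)]
    a2 <- pool[sample.int(length(pool), n_samples, replace = TRUE, prob = probs)]
    both_null <- a1 == 0L & a2 == 0L
    one_null <- xor(a1 == 0L, a2 == 0L)
    vis <- pmax(a1, a2)          # the visible allele when exactly one is null
    a1[one_null] <- vis[one_null]
    a2[one_null] <- vis[one_null]
    miss <- both_null | (runif(n_samples) < missing_rate)
    a1[miss] <- NA_integer_
    a2[miss] <- NA_integer_
    rows[[l]] <- data.frame(sample = samples, locus = l,
                            allele1 = a1, allele2 = a2,
                            stringsAsFactors = FALSE)
  }
  tab <- genotype_table(do.call(rbind, rows), samples = samples,
                        loci = names(loci_specs))
  attr(tab, "truth") <- loci_specs
  tab
}

#' Published 24-locus reference panel summary
#'
#' The per-locus characterization table of the 24 polymorphic
#' microsatellite markers developed for *Apodemus semotus* (sample size,
#' allele-size range, allele count, heterozygosities, HWE p-value, repeat
#' motif, source chromosome and the closest linked protein-coding gene),
#' shipped as packaged plain-text data.
#'
#' @return data.frame with 24 rows and columns `locus`, `chromosome`,
#'   `motif`, `n_repeats`, `N`, `size_min`, `size_max`, `N_A`, `H_E`,
#'   `H_O`, `P_HWE`, `linked_gene` (`NA` when no gene passed the
#'   dual-evidence criteria within 100 kbp).
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "table1_apodemus_semotus.csv",
                      package = "msatdev", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE,
           colClasses = c(locus = "character", chromosome = "character"))
}

#' Simulate a cross-species amplification matrix with a transfer gradient
#'
#' Builds a synthetic amplification score table in which per-locus success
#' probability decays with a species' phylogenetic distance from the source
#' species, for exercising the cross-amplification summaries.
#'
#' @param species character vector, ordered from closest to most distant.
#' @param n_loci number of loci.
#' @param n_samples samples per species (default 5).
#' @param p_close,p_far success probability for the closest and most distant
#'   species; intermediate species are interpolated linearly.
#' @param seed integer seed.
#' @return an [amplification_matrix].
#' @export
make_amplification <- function(species, n_loci = 59L, n_samples = 5L,
                               p_close = 0.9, p_far = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  loci <- sprintf("L%03d", seq_len(n_loci))
  ps <- seq(p_close, p_far, length.out = length(species))
  rows <- list()
  for (i in seq_along(species)) {
    # locus-level transferability: a locus either transfers or not, then
    # per-sample success is near-deterministic given transfer
    transfers <- runif(n_loci) < ps[i]
    for (j in seq_len(n_loci)) {
      succ <- if (transfers[j]) rbinom(n_samples, 1L, 0.95) else
        rbinom(n_samples, 1L, 0.02)
      rows[[length(rows) + 1L]] <- data.frame(
        species = species[i], sample = sprintf("%s_%d", species[i],
                                               seq_len(n_samples)),
        locus = loci[j], success = succ, stringsAsFactors = FALSE
      )
    }
  }
  amplification_matrix(do.call(rbind, rows))
}
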