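# Distance between two 0-based half-open intervals on the same scaffold:
# 0 if they overlap or touch end-to-start, else the size of the gap.
interval_gap <- function(a_start, a_end, b_start, b_end) {
  pmax(0L, pmax(b_start - a_end, a_start - b_end))
}

# choose the feature set used for nearest-exon distances: exons, falling back
# to CDS, falling back to gene spans (logged)
distance_features <- function(annotation) {
  ex <- annotation$exons
  if (nrow(ex) > 0 && any(ex$kind == "exon")) {
    return(ex[ex$kind == "exon", , drop = FALSE])
  }
  if (nrow(ex) > 0 && any(ex$kind == "cds")) {
    msat_log("no exon features; using CDS for nearest-feature distances")
    return(ex[ex$kind == "cds", , drop = FALSE])
  }
  msat_log("no exon/CDS features; using gene spans for nearest-feature distances")
  g <- annotation$genes
  data.frame(gene_id = g$gene_id, scaffold = g$scaffold, start = g$start,
             end = g$end, kind = "gene", stringsAsFactors = FALSE)
}

#' Distance from a locus to its nearest exon
#'
#' Computes the distance in bp between a repeat locus and the closest
#' exon-level feature on the same scaffold: 0 if the intervals overlap,
#' otherwise the gap between their closest ends (half-open arithmetic).
#' Exon features are used when present, falling back to CDS and then gene
#' spans (with a logged note). Strand is ignored; this is pure
#' scaffold-coordinate geometry.
#'
#' @param locus one row of a repeat-locus data.frame (needs `scaffold`,
#'   `start`, `end`).
#' @param annotation a [gene_annotation] object.
#' @return integer distance in bp, or `NA` if the scaffold carries no
#'   feature.
#' @export
nearest_feature_distance <- function(locus, annotation) {
  stopifnot(inherits(annotation, "gene_annotation"), nrow(locus) == 1)
  feats <- distance_features(annotation)
  feats <- feats[feats$scaffold == locus$scaffold, , drop = FALSE]
  if (nrow(feats) == 0) return(NA_integer_)
  # IRanges uses 1-based closed coordinates; width-preserving conversion
  q <- IRanges::IRanges(start = locus$start + 1L, end = locus$end)
  s <- IRanges::IRanges(start = feats$start + 1L, end = feats$end)
  min(IRanges::distance(q, s))
}

#' Genes inside a window around a locus
#'
#' Returns every gene whose span intersects the window
#' `[locus$start - half_width, locus$end + half_width)` on the locus'
#' scaffold, with a signed distance: negative for genes upstream (lower
#' scaffold coordinate) of the locus, positive downstream, 0 when gene and
#' locus overlap. The window is clipped at scaffold bounds when
#' `scaffold_len` is given. Results are sorted by `|distance|`.
#'
#' @param locus one row of a repeat-locus data.frame.
#' @param annotation a [gene_annotation] object.
#' @param half_width window half-width in bp (default 100000, i.e. a 200 kbp
#'   window — the span a selective sweep can plausibly reach).
#' @param scaffold_len optional scaffold length for window clipping.
#' @return data.frame of genes (`gene_id`, `symbol`, `start`, `end`,
#'   `strand`, `distance`).
#' @export
genes_in_window <- function(locus, annotation, half_width = 1e5,
                            scaffold_len = NULL) {
  stopifnot(inherits(annotation, "gene_annotation"), nrow(locus) == 1,
            half_width >= 0)
  g <- annotation$genes
  g <- g[g$scaffold == locus$scaffold, , drop = FALSE]
  w_start <- max(0, locus$start - half_width)
  w_end <- locus$end + half_width
  if (!is.null(scaffold_len)) w_end <- min(w_end, scaffold_len)
  if (nrow(g) == 0) {
    return(cbind(g, data.frame(distance = integer(0))))
  }
  win <- IRanges::IRanges(start = w_start + 1, end = w_end)
  spans <- IRanges::IRanges(start = g$start + 1L, end = g$end)
  hit <- IRanges::overlapsAny(spans, win)
  g <- g[hit, , drop = FALSE]
  if (nrow(g) == 0) {
    return(cbind(g, data.frame(distance = integer(0))))
  }
  gap <- interval_gap(locus$start, locus$end, g$start, g$end)
  sign <- ifelse(gap == 0L, 0L, ifelse(g$start < locus$start, -1L, 1L))
  g$distance <- sign * gap
  g <- g[order(abs(g$distance), g$start), , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Drop predicted/uncharacterized gene symbols
#'
#' Removes the symbol classes used for predicted or uncharacterized genes and
#' microRNAs in mouse-style annotation: `Gm<digit>...`, `LOC<digit>...`,
#' `Mir<digit>...` prefixes and the `...Rik` suffix. Translated homology
#' searches cannot recover these genes, so they are excluded before the
#' dual-evidence comparison. Matching is case-sensitive on the letterforms
#' shown.
#'
#' @param symbols character vector of gene symbols.
#' @return `symbols` with predicted classes removed.
#' @examples
#' exclude_predicted(c("Gm123", "Nrxn1", "LOC456", "Mir21", "2410004B18Rik"))
#' @export
exclude_predicted <- function(symbols) {
  drop <- grepl("^Gm[0-9]", symbols) | grepl("^LOC[0-9]", symbols) |
    grepl("^Mir[0-9]", symbols) | grepl("Rik$", symbols)
  symbols[!drop]
}

#' Dual-evidence gene filter
#'
#' A gene counts as linked to a marker only when it is found both in the
#' annotation window and among the translated homology hits for that locus'
#' query fragment — the annotation side filters the homology side to curb
#' false positives. Predicted/uncharacterized symbols are removed first
#' ([exclude_predicted()]); both sides are compared after
#' [normalize_symbol()].
#'
#' @param window_symbols gene symbols found in the annotation window.
#' @param hit_symbols gene symbols parsed from homology hits (already
#'   E-value-filtered).
#' @return the elements of `window_symbols` passing the filter, in input
#'   order.
#' @export
dual_evidence_filter <- function(window_symbols, hit_symbols) {
  window_symbols <- exclude_predicted(window_symbols)
  keep <- normalize_symbol(window_symbols) %in%
    normalize_symbol(hit_symbols[!is.na(hit_symbols)])
  window_symbols[keep]
}

#' Per-locus linkage report
#'
#' Combines nearest-feature distance, windowed gene lookup and the
#' dual-evidence filter into one row per locus.
#'
#' @param loci repeat-locus data.frame with a unique id in `locus_id` (one is
#'   synthesized from scaffold and start when absent).
#' @param annotation a [gene_annotation] object.
#' @param hits homology-hit data.frame ([read_blast_tab()]); `query_id` must
#'   name the locus a fragment was derived from.
#' @param half_width window half-width in bp (default 100000).
#' @return data.frame with columns `locus_id`, `nearest_exon_distance`,
#'   `n_genes_window`, `linked_genes` (comma-separated symbols), `n_linked`.
#' @export
linkage_report <- function(loci, annotation, hits, half_width = 1e5) {
  if (!"locus_id" %in% names(loci)) {
    loci$locus_id <- paste0(loci$scaffold, ":", loci$start)
  }
  rows <- lapply(seq_len(nrow(loci)), function(i) {
    l <- loci[i, , drop = FALSE]
    wg <- genes_in_window(l, annotation, half_width = half_width)
    kept <- dual_evidence_filter(wg$symbol,
                                 hits$gene_symbol[hits$query_id == l$locus_id])
    data.frame(
      locus_id = l$locus_id,
      nearest_exon_distance = nearest_feature_distance(l, annotation),
      n_genes_window = length(exclude_predicted(wg$symbol)),
      linked_genes = paste(kept, collapse = ","),
      n_linked = length(kept),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize linkage reports into histograms
#'
#' Produces the two headline distributions of a marker-annotation study: the
#' histogram of nearest-exon distances and the histogram of linked-gene
#' counts per locus (bins 0, 1, 2, >=3).
#'
#' @param reports data.frame from [linkage_report()].
#' @param bin_width distance bin width in bp (default 10000).
#' @param count_column which gene count to histogram: `"n_linked"` (default,
#'   after the dual-evidence filter) or `"n_genes_window"`.
#' @return list with elements `distance` (data.frame `bin_start`, `bin_end`,
#'   `count`, `fraction`; loci without any feature are tallied in
#'   `no_feature`) and `gene_count` (data.frame `category`, `count`,
#'   `fraction`). Fractions are over categorized loci and sum to 1 when any
#'   locus is categorized.
#' @export
linkage_summary <- function(reports, bin_width = 1e4,
                            count_column = c("n_linked", "n_genes_window")) {
  stopifnot(bin_width > 0)
  count_column <- match.arg(count_column)
  if (nrow(reports) == 0) {
    return(list(
      distance = data.frame(bin_start = numeric(0), bin_end = numeric(0),
                            count = integer(0), fraction = numeric(0)),
      no_feature = 0L,
      gene_count = data.frame(category = character(0), count = integer(0),
                              fraction = numeric(0))
    ))
  }
  d <- reports$nearest_exon_distance
  no_feature <- sum(is.na(d))
  d <- d[!is.na(d)]
  if (length(d) > 0) {
    bin <- d %/% bin_width
    counts <- table(factor(bin, levels = 0:max(bin)))
    distance <- data.frame(
      bin_start = as.numeric(names(counts)) * bin_width,
      bin_end = (as.numeric(names(counts)) + 1) * bin_width,
      count = as.integer(counts),
      fraction = as.integer(counts) / length(d)
    )
  } else {
    distance <- data.frame(bin_start = numeric(0), bin_end = numeric(0),
                           count = integer(0), fraction = numeric(0))
  }
  k <- reports[[count_column]]
  cat_lvls <- c("0", "1", "2", ">=3")
  category <- ifelse(k >= 3, ">=3", as.character(k))
  gc_counts <- table(factor(category, levels = cat_lvls))
  gene_count <- data.frame(
    category = cat_lvls,
    count = as.integer(gc_counts),
    fraction = as.integer(gc_counts) / length(k)
  )
  list(distance = distance, no_feature = no_feature, gene_count = gene_count)
}
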