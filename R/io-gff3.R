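#' Gene annotation container
#'
#' Bundles gene spans and their exon/CDS children, both as data.frames with
#' 0-based half-open coordinates.
#'
#' @param genes data.frame with columns `gene_id`, `symbol`, `scaffold`,
#'   `start`, `end`, `strand`.
#' @param exons data.frame with columns `gene_id`, `scaffold`, `start`, `end`,
#'   `kind` (`"exon"` or `"cds"`). May have zero rows.
#' @return an object of class `gene_annotation`.
#' @export
gene_annotation <- function(genes, exons) {
  stopifnot(all(c("gene_id", "symbol", "scaffold", "start", "end") %in% names(genes)),
            all(c("gene_id", "scaffold", "start", "end", "kind") %in% names(exons)))
  if (any(genes$end <= genes$start)) stop("gene with end <= start", call. = FALSE)
  if (!"strand" %in% names(genes)) genes$strand <- "?"
  structure(list(genes = genes, exons = exons), class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat("<gene_annotation>", nrow(x$genes), "genes,", nrow(x$exons),
      "exon/CDS features on", length(unique(x$genes$scaffold)), "scaffold(s)\n")
  invisible(x)
}

#' Read gene and exon features from a GFF3 file
#'
#' Parses `gene` features plus their `exon` (or `CDS`) children. GFF3 is
#' 1-based closed; coordinates are converted to the internal 0-based half-open
#' convention on the way in. Exon/CDS features whose `Parent` cannot be
#' resolved to a gene in the file are dropped with a logged count, as are
#' genes lacking any resolvable identifier.
#'
#' @param path path to a GFF3 file.
#' @return a [gene_annotation] object.
#' @details The file is first validated line by line so malformed lines
#'   (fewer than 9 columns) and inverted intervals (`end < start`) are
#'   reported with their line number; parsing of well-formed lines is then
#'   delegated to `rtracklayer::import`. The gene symbol is taken from the
#'   `Name` attribute, falling back to `gene_name` and then the gene id.
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9) {
      stop("malformed GFF3 line ", i, ": expected 9 tab-separated columns, got ",
           length(f), call. = FALSE)
    }
    s <- suppressWarnings(as.integer(f[4])); e <- suppressWarnings(as.integer(f[5]))
    if (is.na(s) || is.na(e)) {
      stop("malformed GFF3 line ", i, ": non-numeric coordinates", call. = FALSE)
    }
    if (e < s) stop("GFF3 line ", i, ": end (", e, ") < start (", s, ")",
                    call. = FALSE)
  }
  gr <- rtracklayer::import(path, format = "gff3")
  meta <- as.data.frame(S4Vectors::mcols(gr))
  type <- as.character(meta$type)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  # convert 1-based closed -> 0-based half-open
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "?"

  is_gene <- type == "gene"
  ids <- if ("ID" %in% names(meta)) as.character(meta$ID) else rep(NA_character_, length(gr))
  gene_ids <- ids[is_gene]
  no_id <- is.na(gene_ids) | !nzchar(gene_ids)
  if (any(no_id)) {
    msat_log("dropped ", sum(no_id), " gene feature(s) without a resolvable id")
  }
  symbol <- rep(NA_character_, length(gr))
  if ("Name" %in% names(meta)) symbol <- as.character(meta$Name)
  if ("gene_name" %in% names(meta)) {
    miss <- is.na(symbol)
    symbol[miss] <- as.character(meta$gene_name)[miss]
  }
  genes <- data.frame(
    gene_id = gene_ids,
    symbol = ifelse(is.na(symbol[is_gene]), gene_ids, symbol[is_gene]),
    scaffold = chrom[is_gene],
    start = start0[is_gene],
    end = end0[is_gene],
    strand = strand[is_gene],
    stringsAsFactors = FALSE
  )[!no_id, , drop = FALSE]

  is_child <- type %in% c("exon", "CDS")
  parent <- rep(NA_character_, length(gr))
  if ("Parent" %in% names(meta)) {
    parent <- vapply(meta$Parent, function(p) {
      if (length(p) == 0) NA_character_ else as.character(p)[1]
    }, character(1))
  }
  child_parent <- parent[is_child]
  known <- child_parent %in% genes$gene_id
  if (any(is_child) && any(!known)) {
    msat_log("dropped ", sum(!known),
             " exon/CDS feature(s) whose Parent is not a gene in the file")
  }
  exons <- data.frame(
    gene_id = child_parent[known],
    scaffold = chrom[is_child][known],
    start = start0[is_child][known],
    end = end0[is_child][known],
    kind = tolower(type[is_child][known]),
    stringsAsFactors = FALSE
  )
  gene_annotation(genes, exons)
}

#' Write a gene annotation to a GFF3 file
#'
#' Inverse of [read_gff3()]: internal 0-based half-open coordinates are
#' converted back to GFF3's 1-based closed convention.
#'
#' @param annotation a [gene_annotation] object.
#' @param path output path.
#' @param source value for the GFF3 source column (default `"msatdev"`).
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotation, path, source = "msatdev") {
  stopifnot(inherits(annotation, "gene_annotation"))
  g <- annotation$genes
  e <- annotation$exons
  gene_lines <- sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                        g$scaffold, source, g$start + 1L, g$end,
                        ifelse(g$strand %in% c("+", "-"), g$strand, "."),
                        g$gene_id, g$symbol)
  lines <- c("##gff-version 3", gene_lines)
  if (nrow(e) > 0) {
    kind <- ifelse(e$kind == "cds", "CDS", "exon")
    strand <- g$strand[match(e$gene_id, g$gene_id)]
    exon_lines <- sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t%s\tID=%s;Parent=%s",
                          e$scaffold, source, kind, e$start + 1L, e$end,
                          ifelse(strand %in% c("+", "-"), strand, "."),
                          ifelse(kind == "CDS", "0", "."),
                          paste0(e$gene_id, ":", kind, ":", seq_len(nrow(e))),
                          e$gene_id)
    lines <- c(lines, exon_lines)
  }
  writeLines(lines, path)
  invisible(path)
}
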