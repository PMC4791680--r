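#' Genotype table
#'
#' A long-format table of co-dominant genotype calls: one row per
#' (sample, locus) pair with two integer allele labels (fragment sizes in bp)
#' or `NA` for a missing call. Allele pairs are unordered; the constructor
#' stores them with `allele1 <= allele2` so equal genotypes compare equal.
#'
#' @param calls data.frame with columns `sample`, `locus`, `allele1`,
#'   `allele2` (integers; both `NA` for a missing call).
#' @param samples,loci optional orderings; default to first appearance.
#' @return an object of class `genotype_table` (a data.frame with `samples`
#'   and `loci` attributes).
#' @export
genotype_table <- function(calls, samples = NULL, loci = NULL) {
  stopifnot(all(c("sample", "locus", "allele1", "allele2") %in% names(calls)))
  calls$sample <- as.character(calls$sample)
  calls$locus <- as.character(calls$locus)
  calls$allele1 <- as.integer(calls$allele1)
  calls$allele2 <- as.integer(calls$allele2)
  half <- xor(is.na(calls$allele1), is.na(calls$allele2))
  if (any(half)) stop("half-missing genotype call(s) at row ",
                      which(half)[1], call. = FALSE)
  swap <- !is.na(calls$allele1) & calls$allele1 > calls$allele2
  tmp <- calls$allele1[swap]
  calls$allele1[swap] <- calls$allele2[swap]
  calls$allele2[swap] <- tmp
  samples <- samples %||% unique(calls$sample)
  loci <- loci %||% unique(calls$locus)
  stopifnot(all(calls$sample %in% samples), all(calls$locus %in% loci))
  if (anyDuplicated(calls[, c("sample", "locus")])) {
    stop("duplicate (sample, locus) call", call. = FALSE)
  }
  structure(calls, class = c("genotype_table", "data.frame"),
            samples = samples, loci = loci)
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("<genotype_table>", length(attr(x, "samples")), "samples x",
      length(attr(x, "loci")), "loci,",
      sum(is.na(x$allele1)), "missing call(s)\n")
  invisible(x)
}

#' Read genotype calls from CSV
#'
#' Expects columns `sample,locus,allele1,allele2`; blank allele cells mean a
#' missing call.
#'
#' @param path path to the CSV file.
#' @return a [genotype_table].
#' @export
read_genotypes <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  genotype_table(df)
}

#' Write a genotype table to CSV
#'
#' @param table a [genotype_table].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE,
            na = "")
  invisible(path)
}

# calls at one locus in sample order; rows with both alleles NA are missing
locus_calls <- function(table, locus) {
  stopifnot(inherits(table, "genotype_table"))
  sub <- table[table$locus == locus, , drop = FALSE]
  if (nrow(sub) == 0) stop("unknown locus ", locus, call. = FALSE)
  sub[match(intersect(attr(table, "samples"), sub$sample), sub$sample), ,
      drop = FALSE]
}

#' Write a genotype table in GenePop format
#'
#' Emits a GenePop 4.x file with 3-digit allele codes: a title line, one locus
#' name per line, a `Pop` line, then one line per sample
#' (`<sample> ,  <6-digit code per locus>`), missing genotype = `000000`.
#' Allele sizes are rank-mapped to codes `001..k` in ascending size order per
#' locus; the size-to-code mapping is written alongside as
#' `<path>.allele_map.csv` so genotypes can be mapped back.
#'
#' @param table a [genotype_table].
#' @param path output path.
#' @param title title line content (default `"msatdev export"`).
#' @return `path`, invisibly. Errors if a locus has more than 999 alleles.
#' @seealso [read_genepop()]
#' @export
write_genepop <- function(table, path, title = "msatdev export") {
  stopifnot(inherits(table, "genotype_table"))
  samples <- attr(table, "samples")
  loci <- attr(table, "loci")
  maps <- lapply(loci, function(l) {
    sub <- table[table$locus == l, , drop = FALSE]
    sizes <- sort(unique(c(sub$allele1, sub$allele2)))
    sizes <- sizes[!is.na(sizes)]
    if (length(sizes) > 999) stop("locus ", l, " has ", length(sizes),
                                  " alleles; GenePop 3-digit codes cap at 999",
                                  call. = FALSE)
    setNames(seq_along(sizes), sizes)
  })
  names(maps) <- loci
  code <- function(size, map) {
    if (is.na(size)) "000" else sprintf("%03d", map[[as.character(size)]])
  }
  sample_lines <- vapply(samples, function(s) {
    codes <- vapply(loci, function(l) {
      row <- table[table$sample == s & table$locus == l, , drop = FALSE]
      if (nrow(row) == 0) return("000000")
      paste0(code(row$allele1[1], maps[[l]]), code(row$allele2[1], maps[[l]]))
    }, character(1))
    paste0(s, " ,  ", paste(codes, collapse = " "))
  }, character(1))
  writeLines(c(title, loci, "Pop", sample_lines), path)
  map_df <- do.call(rbind, lapply(loci, function(l) {
    data.frame(locus = l, size = as.integer(names(maps[[l]])),
               code = sprintf("%03d", unname(maps[[l]])),
               stringsAsFactors = FALSE)
  }))
  write.csv(map_df, paste0(path, ".allele_map.csv"), row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Read a GenePop file written by [write_genepop()]
#'
#' Parses a single-population GenePop file with 3-digit (6 digits per locus)
#' codes. If the companion `<path>.allele_map.csv` exists, codes are mapped
#' back to allele sizes; otherwise the codes themselves are used as labels.
#'
#' @param path path to the GenePop file.
#' @return a [genotype_table].
#' @export
read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  pop_at <- which(trimws(tolower(lines)) == "pop")[1]
  if (is.na(pop_at)) stop("no Pop line in ", path, call. = FALSE)
  loci <- trimws(lines[2:(pop_at - 1)])
  loci <- unlist(strsplit(loci, ",\\s*"))  # GenePop allows comma-separated locus lists
  map_path <- paste0(path, ".allele_map.csv")
  map <- if (file.exists(map_path)) read.csv(map_path, colClasses =
    c("character", "integer", "character")) else NULL
  decode <- function(locus, code3) {
    if (code3 == "000") return(NA_integer_)
    if (is.null(map)) return(as.integer(code3))
    hit <- map$size[map$locus == locus & map$code == code3]
    if (length(hit) != 1) stop("no allele-map entry for ", locus, " code ",
                               code3, call. = FALSE)
    hit
  }
  rows <- lapply(lines[(pop_at + 1):length(lines)], function(ln) {
    if (!nzchar(trimws(ln))) return(NULL)
    parts <- strsplit(ln, ",", fixed = TRUE)[[1]]
    if (length(parts) < 2) stop("malformed GenePop sample line: ", ln,
                                call. = FALSE)
    sample <- trimws(parts[1])
    codes <- strsplit(trimws(paste(parts[-1], collapse = ",")), "\\s+")[[1]]
    if (length(codes) != length(loci)) {
      stop("sample ", sample, ": ", length(codes), " genotypes for ",
           length(loci), " loci", call. = FALSE)
    }
    data.frame(sample = sample, locus = loci,
               allele1 = vapply(seq_along(loci), function(i)
                 decode(loci[i], substr(codes[i], 1, 3)), integer(1)),
               allele2 = vapply(seq_along(loci), function(i)
                 decode(loci[i], substr(codes[i], 4, 6)), integer(1)),
               stringsAsFactors = FALSE)
  })
  genotype_table(do.call(rbind, rows), loci = loci)
}
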