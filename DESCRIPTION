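Package: msatdev
Title: Informative Microsatellite Marker Development from Reference-Mapped Scaffolds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for developing "informative" microsatellite (SSR) markers for a
    non-model species whose shotgun reads have been mapped against a related model
    genome. Detects perfect tandem repeats in scaffolds under configurable screening
    rules (tetranucleotide motifs with at least eight repeats by default), prepares
    primer-design regions with designability checks and universal 5' tags, annotates
    each locus with nearby protein-coding genes via a windowed dual-evidence
    (translated homology intersected with annotation) filter, computes per-locus
    genotype statistics (allele counts, observed and unbiased expected
    heterozygosity, exact Hardy-Weinberg tests, null-allele estimators), and
    summarizes cross-species amplification success. Includes seeded synthetic-data
    generators with recorded ground truth so the whole pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
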