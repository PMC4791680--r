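---
title: "Developing annotated microsatellite markers from reference-mapped scaffolds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Developing annotated microsatellite markers from reference-mapped scaffolds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msatdev)
```

## The problem and the approach

Microsatellite markers developed by cloning are anonymous: usable for
genotyping, but silent about genomic context. When a related model genome
exists, an alternative is to map the study species' shotgun reads against
it and develop markers from the mapped consensus. The scaffolds inherit the
reference's coordinate system, so every marker gains a location, a
chromosome assignment, a distance to the nearest exon, and a candidate list
of neighbouring protein-coding genes. `msatdev` implements everything
downstream of the mapping itself: the mapper's output (a FASTA of
scaffolds, typically containing `N` runs where coverage failed) is this
package's input.

Two assumptions shape the design. First, the scaffolds are a *conserved
subset* of the genome — mapping only succeeds where the two species are
similar — so markers developed here are biased toward conserved regions;
that is a feature for cross-species transferability and a caveat for
genome-wide representativeness. Second, annotation is borrowed, not owned:
a gene's presence near a scaffold position is evidence from the model
genome, which is why linkage claims require the dual-evidence filter
described below.

## Repeat screening

`find_perfect_repeats()` reports every maximal run of at least
`min_repeats` exact whole copies of a `period`-length unit. The
implementation compares the sequence with itself shifted by `period`
(positions where `s[i] == s[i + period]`, both unambiguous) and reads
maximal matching stretches off a run-length encoding; a stretch of length
`L` yields `floor(L / period) + 1` whole copies from its leftmost position.
Conventions, chosen to be deterministic and oracle-checkable:

* a run is reported once, anchored at its leftmost start, and the reported
  motif is the unit beginning there; `canonical_motif()` (lexicographic
  minimum over rotations of the unit and of its reverse complement) gives
  the class label;
* partial trailing copies neither count toward `n_repeats` nor extend
  `[start, end)` — repeats are counted in whole units;
* runs containing `N` are excluded, as are homopolymer units (`AAAA` is a
  period-1 repeat, not a tetranucleotide motif). Units with internal
  periodicity greater than 1 (`ACAC` at period 4) are *kept*: the screening
  rule excludes only the homopolymer degeneracy, and down-stream motif
  classes keep such loci distinguishable. Only perfect repeats are
  detected; imperfect-repeat detection is out of scope.

Defaults — period 4, at least 8 copies, scaffolds strictly longer than
1 Mbp — reproduce the screening rule of the rodent study the package's
reference panel comes from; periods 2–6 are supported.

## Marker design

`extract_flanks()` takes `flank_len` (default 200 bp) on each side of the
repeat, clipping at scaffold ends (clipping is recorded; a flank shorter
than the longest primer, 24 bp, fails immediately).
`designability_check()` then requires each flank to contain at least 24
contiguous unambiguous bases and at most 20 % `N`, and the product-size
arithmetic `repeat + 2 × 20 ≤ 450` bp to hold. The 200 bp default keeps a
450 bp product reachable for repeats up to ~410 bp; the 0.2 `N`-fraction
cap is this package's choice for mapped consensi, whose flanks legitimately
carry gap runs — both are configurable in `primer_params()`. Melting
temperatures (57 °C optimum, 54–65 °C range) and primer lengths (20–24 bp)
are recorded in `primer_params()` and handed to Primer3; the thermodynamics
are deliberately not reimplemented, since region preparation — not primer
energetics — is where this pipeline contributes.

`select_panel()` stratifies by chromosome group, drawing uniformly between
`k_min = 2` and `k_max = 5` designable candidates per group without
replacement, with configurable exclusions (the reference design excluded
chromosome 7 and the sex chromosomes) and a mandatory seed, so a panel is
reproducible from its seed.

## Gene linkage and the dual-evidence filter

All coordinates are internally 0-based half-open; GFF3 and BLAST
coordinates are converted exactly once, at the file boundary. Distance
between intervals is 0 on overlap and the gap between closest ends
otherwise — the convention is stated explicitly because interval "distance"
is otherwise ambiguous. Strand is ignored for geometry and retained in
output.

`genes_in_window()` anchors a ±100 kbp window on the repeat interval (the
annotation side), while the homology side queries hits derived from the
primer-flanked fragment when primer coordinates exist — mirroring the two
slightly different region definitions that arise naturally in this design.
The 200 kbp total span is the range a selective sweep might plausibly
affect. A gene is *linked* only when it passes both sides
(`dual_evidence_filter()`): present in the window **and** among homology
hits at E ≤ 1e-6 (inclusive threshold — common practice where strictness is
unstated). Predicted/uncharacterized classes (`Gm#`, `LOC#`, `Mir#`,
`…Rik`) are removed first, because translated homology cannot recover them
and counting them would inflate the annotation side only. Symbols are
compared case-insensitively after stripping one trailing isoform suffix
(`.N`/`-N`) and, for pipe-delimited subject ids, taking the last token;
how homology subject accessions map to annotation symbols is genuinely
underdetermined, so the rule is deliberately minimal and normalization is
logged. Gene-level identity decides window membership; exon intervals are
used only for nearest-exon distances, falling back to CDS and then gene
spans when absent (logged).

## Genotype statistics

`H_E` uses Nei's (1978) small-sample correction `2N/(2N−1)·(1−Σp²)`,
matching the estimator of the standard marker-characterization programs;
the uncorrected form is available (`correct = FALSE`). For `N = 1` the
correction is undefined and the uncorrected value is returned with a
warning. Missing genotypes are excluded locus-wise — per-locus `N` varies,
as in any real panel — and never imputed.

The HWE test is the exact *probability* test conditional on allele counts:
under the Levene distribution a genotype-count configuration `{n_ij}` has
probability `N!·∏a_k!·2^h / ((2N)!·∏n_ij!)` with `h` heterozygotes, and the
p-value totals the probability of configurations no more probable than the
observed one. Configurations are enumerated recursively (row-wise over the
upper-triangular count matrix) when their number stays within `enum_cap`
(default 1e5); beyond that, the null is sampled by re-pairing the `2N`
allele copies (`reps` default 1e5, explicit seed), and the p-value is the
proportion of sampled configurations — observed included, hence
`(hits+1)/(reps+1)`, which cannot return 0 — with probability at most the
observed. Probability comparisons happen in log space with a relative
tolerance of ~1e-9 so floating-point ties count as ties. Degenerate loci
(`N < 2` or one allele) return p = 1 with the method recorded. No
multiple-testing correction is applied — the reference panel reports raw
per-locus p-values — and the method (enumeration/Monte Carlo) is always
recorded because published tables rarely state which was used.

Null-allele estimators are the Chakraborty ratio `(H_E−H_O)/(H_E+H_O)` and
Brookfield-1 `(H_E−H_O)/(1+H_E)`; negative estimates are floored at zero
with the raw value retained, since an excess of heterozygotes is
informative even when the frequency estimate is not. The van Oosterhout and
Brookfield-2 estimators, stutter diagnostics, and linkage-disequilibrium
tests are out of scope.

## Cross-species amplification

Success is a wet-lab judgment (a product of expected size, no smearing)
supplied as a 0/1/untested label — never computed from traces. Untested
samples are excluded from denominators; threshold comparisons are inclusive
("80 % or better"). `species_table()` ranks species by their count at the
highest threshold, ties preserving input order.

## What the generators emulate — and what they do not

`make_scaffolds()` produces i.i.d. uniform ACGT background with planted `N`
runs and planted repeats, and *rejection-checks* the background: a draw is
regenerated unless the detector's output equals the planted truth exactly,
so the recorded truth is exhaustive and recall/precision are well-defined.
`make_genotypes()` draws genotypes at Hardy–Weinberg proportions from a
pool that may include a null allele (visible frequencies scaled by
`1 − r`); null homozygotes become missing, null heterozygotes surface as
visible homozygotes — the standard null-allele observation model.
`make_amplification()` plants a monotone transfer gradient across species.

Real scaffolds are not i.i.d.: they carry compositional bias, imperfect
and compound repeats, paralogy, and mapping artefacts correlated with
divergence. Real genotype panels add stutter, allele dropout, and scoring
error beyond the pure null-allele model. Passing tests therefore establish
correctness of the computations under their stated models — maximality,
exactness of the conditional distribution, estimator algebra — not
robustness of marker yield on any particular genome.

The default generator conditions mirror the reference study where it
states them (24-individual genotype panels; 5 samples per species in
cross-amplification; tetranucleotide motifs at ≥ 8 copies) and otherwise
use sizes a desk-scale study would call realistic: scaffolds of 8–300 kbp
in tests (the 1 Mbp gate is exercised by construction rather than by
generating megabase sequences), 12 planted loci for recovery checks,
500-individual panels for estimator recovery, 200 replicates for
null-allele calibration, and 10,000 simulated panels for the test-size
check.

## Known limitations

* Only perfect repeats are detected; compound and interrupted
  microsatellites are invisible to the screen.
* The linkage annotation is only as good as the borrowed annotation and
  the homology search; the dual filter trades sensitivity for precision by
  construction.
* The GenePop writer emits a single population with 3-digit rank codes; the
  size-to-code map is written alongside because rank codes alone lose the
  fragment sizes.
* Enumeration of the HWE null grows combinatorially with allele count; the
  Monte-Carlo fallback is accurate to its sampling error, which is reported
  through the recorded method and replicate count rather than hidden.
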