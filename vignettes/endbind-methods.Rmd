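---
title: "Gene-end binding analysis with endbind: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-end binding analysis with endbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endbind)
```

## The problem

MYC-family transcription factors are usually analysed as promoter binders,
but a reproducible minority of their ChIP-seq peaks lie within a few
kilobases of transcription end sites (TES). Whether a gene binds a factor
pair at its 5′ end, its 3′ end, both, or neither turns out to correlate with
expression level, with read-through transcription past the TES, and with
direct TSS–TES chromatin contacts. `endbind` implements that analysis
framework as composable, deterministic functions over standard genomics
formats, and validates every stage against a synthetic genome with planted
ground truth.

## Coordinate and window conventions

Everything inside the package is 1-based and closed, the GTF convention.
BED-dialect inputs (narrowPeak, bedGraph, BEDPE, cofactor BED) are converted
at ingestion, and every emitted table states the convention in its header.

Gene ends are represented as *anchor sets*: each annotated transcript
contributes one TSS and one TES anchor, strand-aware, and anchors of the same
gene end within 10 bp are merged to the outermost position (most upstream
TSS, most downstream TES). The merge radius exists only to collapse
near-duplicate transcript ends that would otherwise double-count a single
biological end; anchors further apart are kept and can each capture peaks.

A peak belongs to a gene end when its summit lies within ±`radius` of an
anchor (default 2500 bp, with 1000 bp as the preset for compact genomes such
as *D. melanogaster*). The summit, not the peak interval, is the membership
point: peak positions are single distances from an anchor throughout the
analysis, and an interval-overlap mode is available where broader capture is
wanted. A summit within the windows of two genes is assigned to both genes;
within several anchors of the *same* gene end it yields one assignment
against the nearest anchor.

### Ambiguity between head-to-tail neighbours

When two genes run head-to-tail with a short intergenic gap, one summit can
be read as TES binding of the upstream gene or TSS binding of the downstream
gene. Such assignments are *flagged* on both rows, never removed: category
classification keeps them (the configuration scheme draws no distinction),
while signal-level and TES-specific analyses drop them. Both behaviours are
explicit arguments rather than hidden pipeline state.

## The 16-category scheme

Each gene's 5′ and 3′ states over a factor pair (none / A only / B only /
both) form 16 ordered pairs, numbered 1–16. Only some cells of the numbering
are fixed by the scheme's defining constraints (3, 4, 7, 9, 10, 12, 16, the
5′-both triple 10–12, and the TES-only triple 2, 6, 13); the remaining cells
are completed by a package default that is explicitly a convention, not
recovered ground truth. The map is therefore a 16-row configuration table validated by
`validate_category_map()` — any bijection satisfying the textual constraints
can be substituted — and all downstream code keys on the state pair, never on
the integer. Factor names are parameters, so the same scheme applies to
MYCN, MXD-family members, or any other pair.

## Signal metrics and retention

Region classes partition peaks with precedence TSS > TES > intragenic >
distal; "intragenic" means inside a gene span but beyond both end windows,
"distal" outside all spans and windows. Distance strata around anchors use
the gene-oriented offset sign with a 100 bp "overlapping" band — a width the
source figures do not state, chosen here as roughly one nucleosome.

Retention kinetics track *sites*, keyed by (gene, end, anchor), rather than
peak intervals, because summit jitter between timepoints would break interval
identity. "Percent remaining bound" is presence/absence of any called peak
at the site; relative signal is the mean signal at retained sites divided by
the mean *baseline* signal at those same sites (a matched-site ratio), so a
uniform 50% signal decay reads back as exactly 0.5 regardless of which sites
were lost. Affinity tiers split baseline signals at a configurable quantile
(default the median).

## DoG read-through

Read-through is the ratio of stranded coverage mass in the 500 bp window
just downstream of the most-downstream TES anchor to the mass in the 500 bp
window just upstream of it. The upstream window excludes the TES base
itself, which makes the two windows exact mirror images under strand flip
plus coordinate reflection — a symmetry the tests exploit. Windows are equal
length, so the count ratio equals the density ratio and is invariant to
global depth scaling. Genes with upstream mass below `min_upstream`
(default 10) are flagged rather than given unstable ratios, and a downstream
window overlapping another same-strand gene is masked outright, since a
neighbour's transcription is not read-through. Cross-condition changes use
log2 ratios of pseudocount-stabilised (+0.5) fractions.

## Loops, co-occupancy and dyads

Loop anchors are assigned to gene ends by their midpoints under the same
window rule as peaks (anchors are wide; the midpoint is the default
convention, with any-overlap available). A gene's contact profile has three
flags — a direct TSS–TES loop, additional TSS contacts, additional TES
contacts — defining groups A–H. "Additional" contacts require the second
anchor to land outside the gene's opposite end window, and loops whose two
anchors fall in one window are discarded as self-loops. The B/C orientation
(TSS-only versus TES-only extra contacts) is fixed by convention here and
excluded from ground-truth comparisons. Looping frequency per category is
reported under both defensible denominators: fraction of genes with a direct
loop, and mean direct loops per gene.

Co-occupancy profiles are computed per cofactor as the percentage of
anchor-factor regions whose 250 bp bin is overlapped by at least one peak,
then z-scored per factor across all bins of all four region classes.
Per-bin percentages (rather than per-region) retain the profile shape the
heat-map display implies. Zero-variance factors get a zero row and a flag
instead of NaNs.

Dyads are head-to-tail pairs where some summit lies within the window of
*both* facing anchors and neither gene carries any other binding — at any
timepoint — in its vicinity (default: gene span ± radius; a window-restricted
mode is provided because "vicinity" admits more than one reasonable
definition). Expression responses are called at the timepoint of maximal
|log2 fold change| versus baseline with a 1.5-fold threshold, a documented
convention; the full per-timepoint matrix is also returned.

## The synthetic genome

`simulate_bundle()` builds a single-chromosome genome of isolated genes and
adjacent pairs in all three orientations, with gene lengths of 7–15 kb,
facing-anchor gaps of 0.8–4 kb (0.8–2 kb for dyad pairs) and inter-unit gaps
of 12–20 kb. Binding states are drawn from a 16-category mix in which the
unbound state dominates and the 5′-both configuration is the most common
bound one; signals are lognormal in two affinity tiers; coverage is Poisson
in 50 bp tiles with gene-specific read-through tails (length 500 bp +
Exp(mean 2 kb), so the measuring window always lies inside the tail and the
fraction estimator stays unbiased); loops, cofactor peaks and
category-dependent lognormal expression complete the bundle. Two timepoints
are emitted, with low-affinity dyad sites present only after induction.

One placement rule makes planted truth exactly recoverable while keeping
closely spaced pairs: peaks and loop anchors at the *facing* end of a paired
gene are placed on the outer side of the anchor with magnitude at least
`radius − gap + margin`, so they fall in exactly one gene's window; only
deliberate dyad peaks sit mid-gap and assign to both neighbours. The
generator emulates the statistical structure of real end-binding data — not
its sequence content, replicate structure, peak-calling noise, or
chromosome-scale heterogeneity — so passing recovery tests demonstrates
correctness of the analysis logic, not robustness to upstream calling
errors.

Default problem sizes (500 genes for end-to-end checks, 200 for module
tests, 200–500 simulation replicates for test calibration) were chosen so
the whole validation suite runs in minutes on a laptop while leaving
multinomial sampling error well below the tested tolerances.

## Numerical and degenerate-input choices

* Coverage intervals are prorated by overlapped length, so window masses are
  exact for any tile alignment.
* Ties (a summit equidistant from two genes' anchors) assign to both genes,
  with deterministic ordering by gene id.
* Empty region classes summarise as n = 0 with no mean; degenerate
  comparison groups are skipped with a message rather than produce NaN
  statistics; zero count cells in biotype contingency tables fall back to
  Fisher's exact test, flagged as such.
* All randomness flows through one seeded generator; bundle files contain no
  timestamps, so a configuration is checksum-reproducible byte for byte.

## Known limitations

The package does not call peaks, loops or differential expression; it
consumes their standard file formats. DoG quantification uses the fixed
500 bp ratio, not arbitrary-length read-through segment discovery. The
16-way numbering beyond the textually constrained cells, the B/C loop-group
orientation, and the 1.5-fold dyad response threshold are documented
conventions, and analyses that depend on them treat the underlying state
pairs and flags as primary.
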