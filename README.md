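# endbind

Transcription factors of the MYC network are textbook promoter binders, yet a
substantial minority of their ChIP-seq peaks sit at the *other* end of genes,
within a few kilobases of transcription end sites (TES). `endbind` is an R
toolkit for analysing that 3′-end binding mode: it assigns peaks to gene-end
windows, classifies genes by the joint 5′/3′ binding configuration of a factor
pair, and quantifies the functional correlates of TES-proximal binding —
read-through (downstream-of-gene, DoG) transcription, TSS–TES chromatin
looping, co-occupancy with other regulators, and regulation of head-to-tail
gene dyads from a single shared intergenic site.

## What it computes

For genes *g* with TSS/TES anchor sets derived from every annotated
transcript, and peak summits *s*:

* **End assignment** — a peak is assigned to a gene end when
  |*s* − anchor| ≤ *r* (default *r* = 2.5 kb; 1 kb preset for compact
  genomes). A summit within *r* of anchors of two genes is assigned to both;
  peaks readable as both the TES of one gene and the TSS of its head-to-tail
  neighbour are flagged ambiguous.
* **16-category classification** — each gene's (5′ state, 3′ state) over a
  factor pair (canonically MYC and MAX), with state ∈ {none, A only, B only,
  A and B}, mapped to categories 1–16 (16 = unbound; 9 = both factors at the
  5′ end only; 2/6/13 = TES-only binding). Peak multiplicity is ignored.
* **DoG read-through** — per gene, the ratio of stranded coverage mass in the
  500 bp window just past the most-downstream TES to the mass in the 500 bp
  window just before it; groups compared by Wilcoxon rank-sum test.
* **Loop groups A–H** — ChIA-PET anchors assigned to gene ends with the same
  window rule; genes classified by presence of a direct TSS–TES loop and of
  additional TSS/TES contacts, cross-tabulated with the 16 categories.
* **Co-occupancy z-profiles** — per cofactor, the percentage of anchor-factor
  regions (TSS / TES / intragenic enhancer / distal enhancer classes)
  overlapped per 250 bp bin, z-scored within factor.
* **Dyads** — head-to-tail pairs whose *only* binding is one shared
  intergenic site, with each flank's expression response (positive / none /
  negative) called from baseline-normalised log2 fold changes.
* **Retention kinetics** — fraction of baseline sites still bound, and their
  matched relative signal, across a perturbation time course.

A deterministic synthetic-data generator (`simulate_bundle()`) emits an
internally consistent annotation, narrowPeak, bedGraph, BEDPE, cofactor BED
and expression fixture set with recorded ground truth for every analysis, so
the whole pipeline is validated end to end against planted truth.

## Worked example

```r
library(endbind)

bundle <- simulate_bundle(sim_config(seed = 1, n_genes = 200), write = FALSE)
rel    <- pair_relations(bundle$genes)
t0     <- bundle$peaks[bundle$peaks$sample == "t0", ]
asn    <- flag_ambiguous(assign_peaks(t0, bundle$genes), rel)
calls  <- classify_end_binding(asn, bundle$genes)

head(category_summary(calls), 4)
#>   category n fraction
#> 1        1 7    0.035
#> 2        2 7    0.035
#> 3        3 0    0.000
#> 4        4 0    0.000

mean(calls$state_3p != "none")   # 23% of genes carry 3'-end binding
#> [1] 0.23

dog <- count_dog_windows(bundle$coverage, bundle$genes)
grp <- setNames(ifelse(calls$state_3p == "none", "TES_unbound", "TES_bound"),
                calls$gene_id)
compare_dog_groups(dog, grp)[c("medians", "p_value")]
#> $medians
#>   TES_bound TES_unbound
#>  0.24858054  0.09812582
#> $p_value
#> [1] 2.024775e-12
```

TES-bound genes show a ~2.5-fold higher median read-through fraction than
unbound genes, recovering the planted effect (simulated bound/unbound genes
draw DoG fractions with means 0.3 and 0.1).

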