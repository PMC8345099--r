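---
title: "Methods: differential enhancer analysis for platinum-resistance studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential enhancer analysis for platinum-resistance studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enhancerdiff)
```

## The problem this package addresses

Epithelial ovarian cancer cells that survive repeated cisplatin exposure can
acquire resistance without recurrent driver mutations: the phenotype is
carried largely by a reorganization of the active-enhancer landscape, read
out as gains and losses of H3K27ac (and H3K9ac) at distal regulatory
elements. A typical study design profiles a sensitive cell line and its
resistant derivative by ChIP-seq, asks which acetylation peaks change,
links those peaks to genes and expression, checks whether the changes could
be genetic (variant accumulation at the same loci), screens for chromatin
factors whose knockdown synergizes with cisplatin, and finally asks whether
suppressing such a factor (for instance MBD3, the structural core of the
NuRD complex) reverts the resistance-associated acetylation pattern.

`enhancerdiff` implements the computational arm of that design as a set of
small, testable operations plus a config-driven pipeline. Alignment, peak
calling and variant calling are treated as upstream: the package consumes
their standard outputs (BED, bedGraph, VCF) and never re-implements them.

## Coordinate conventions

Regions are BED-style 0-based half-open intervals `[s, e)`; variant and TSS
positions are 1-based. All conversions are centralized in a single pair of
helpers that translate both into 1-based closed ranges for overlap work, so
the off-by-one rule lives in exactly one tested place: a variant at
position `p` overlaps `[s, e)` iff `s < p <= e`. Peaks are unstranded
(acetylation is not strand-specific); TSS strand is kept to sign distances.

## Signal matrices and normalization

`extract_signal_matrix()` evaluates per-bp coverage in a window (default
10 kb at 100 bp bins) centered on each peak midpoint, the midpoint of an
even-width region resolving leftward (`floor((s+e)/2)`). Positions off the
chromosome or outside track coverage contribute zero, so the matrix never
contains missing values.

`quantile_normalize()` equalizes the whole signal distribution of each
sample: values are replaced by the cross-sample mean of sorted values at
the same rank, tied values receiving the mean over their tied rank block.
Normalization operates on the flattened region-by-bin vector per sample
rather than per bin position: the intent is to make whole ChIP-seq signal
distributions comparable, not to force every bin position to a common
distribution. With a single sample the operation is the identity (with a
warning). The tie rule means that samples containing ties end up with
marginals equal only up to tie-block averaging; for continuous coverage
values this is immaterial.

Quantitative ChIP-qPCR values are normalized to input and to the exogenous
spike-in chromatin (`normalize_chip_qpcr()`: target/input divided by
spike-target/spike-input, expressed relative to a reference condition), and
RT-qPCR expression as a ratio of ratios against a reference gene and a
control sample (`relative_expression()`, with a `2^-ddCt` wrapper for Ct
input at fixed efficiency 2 — the efficiency is not estimated).

## Differential regions

Two complementary paths identify regions with differential acetylation,
mirroring how such analyses are usually presented (a clustered heatmap plus
an explicit filter):

* `cluster_regions()` runs K-means (default `K = 3`, fixed seed and restart
  count, so results are reproducible) on per-region log2 ratio profiles
  `log2((s2+1)/(s1+1))`. The pseudocount of 1 normalized unit keeps empty
  bins finite. Clusters are labelled by their mean log ratio: above
  `log2(1.3)` up, below `log2(0.75)` down, otherwise common. The default
  feature vector is the profile over the *region body* rescaled to 20
  points (scale-regions style). The alternative — raw 10 kb window
  profiles — makes the Euclidean distance between two regions depend
  strongly on their widths: a 1 kb up-regulated peak has only 10 elevated
  bins out of 100 and sits closer to the common centroid than to the up
  centroid, a geometry artifact with no biological meaning. Body-scaled
  profiles remove the width dependence while preserving per-bin shape;
  `features = "window"` is retained for comparison. `K` itself is a free
  parameter: three clusters reflect the expected structure (one common and
  two differential classes).
* `filter_differential_peaks()` applies the explicit rule: width above
  2 kb, peak intensity above 1000 normalized units, and pseudocounted fold
  change `(m2+1)/(m1+1)` above 1.3 (up) or below 0.75 (down). "Intensity"
  defaults to the *maximum* of the two condition means so that a peak fully
  silenced in one condition remains callable (a mean-of-means mode is
  provided). All thresholds are exposed; the monotone behaviour of the
  calls in each threshold is property-tested.

`annotate_nearest_tss()` reports, per region, the nearest TSS by absolute
midpoint distance with a signed convention (positive downstream of the
TSS; sign flips on minus-strand genes) and lexicographic gene-name
tie-breaking, so results are deterministic. `correlate_marks()` reports
Pearson and Spearman correlation of per-region mean signals of two marks.
`find_inverse_regions()` intersects up-calls of one comparison with
down-calls of another (and vice versa); default semantics is any overlap,
because both comparisons usually share one peak universe — a reciprocal
overlap fraction is available when they do not.

## Super-enhancers

`stitch_peaks()` merges same-chromosome peaks transitively when the gap is
at most the stitching distance (default 12,500 bp, the canonical choice),
with optional promoter exclusion. `call_superenhancers()` sorts stitched
enhancers by total signal (per-constituent mean coverage times width,
summed), scales the rank curve to the unit square, and cuts at the signal
of the first rank where the discrete slope exceeds 1. The discrete rule is
chosen over spline fitting deliberately: it is deterministic, has no
smoothing parameter, and agrees with a grid search for the slope-1 point on
every tested curve. An all-equal signal vector yields no super-enhancers
(flat curve), with a warning. No input subtraction or copy-number
correction is applied to the ranking signal.

## Variant density

`count_variants_per_region()` counts variant positions per region under the
overlap rule above; a variant in two overlapping regions counts in both.
Densities are per kb because region widths differ systematically between
classes — comparing raw counts would confound width with rate.
`compare_density()` uses a two-sided Mann-Whitney U test: exact when both
groups have at most 8 tie-free observations, otherwise the normal
approximation with tie correction and *without* continuity correction, so
that identical groups return p = 1 exactly. All-tied input returns p = 1
with a warning rather than NaN.

## Gene-level integration

`cumulative_signal_per_gene()` sums region signal over nearest-TSS gene
assignments. `resistance_index()` z-scores each gene across the panel and
scores each sample as mean z of signature-up genes minus mean z of
signature-down genes; GI50 groups (threshold 20 uM) are compared by the
same Mann-Whitney machinery. The mean-z difference form is a documented
reconstruction: published resistance scores name their ingredients more
often than their arithmetic, and this form is symmetric (swapping the
signature halves exactly negates every index), scale-free, and calibrated
under the null. Constant genes contribute z = 0 rather than NaN.

`combined_rank_score()` ranks genes by
`log2FC x (-log10 FDR) x log10(1 + cumulative signal)`. This product form
is likewise a reconstruction from the three named ingredients: each factor
is zero at its null value, so a gene must move in expression, do so
reproducibly, and carry acetylation signal to rank at all. FDR = 0 is
clamped to the double-precision floor with a warning. Ties break by FDR
then gene name.

`enrich_gene_sets()` is an upper-tail hypergeometric test on nearest-TSS
gene assignments with Benjamini-Hochberg adjustment, reporting sets at
p <= 0.05. This deliberately simplifies locus-length-aware enrichment
regressions: genes with long loci or many peaks are more likely to be
selected by proximity assignment, so enrichment p-values here carry a
length bias that a regression-based method would model. The universe is
the set of assayable genes (those with at least one TSS in the
annotation), not the whole genome.

## Pooled shRNA screen

Counts are normalized to reads per million with a pseudocount of 1 (which
both prevents division by zero and caps the influence of guides sequenced
near zero). Depletion is day-14 over pool per shRNA, with per-replicate
pools matched by replicate and a single sequenced pool broadcast.
`gene_depletion()` takes the geometric mean over all shRNA-by-replicate
ratios of a gene — pooled rather than nested, which is order-invariant and
matches a "geometric mean over n = 3" readout; a nested mode is retained.
`differential_depletion()` ranks genes by `D = depletion_cpt /
depletion_vehicle` ascending. Because rpm normalization cancels any
per-sample scaling, the ranking is invariant to sequencing depth, which is
property-tested. Empirical p-values come from permuting the shRNA-to-gene
assignment (default 1000 permutations, seeded), one-sided for depletion.
Hit calling (`D` at most 0.5 with at least 2 supporting shRNAs) is an
explicit reconstruction — dropout screens rarely publish their exact
significance rule — and every part of it is exposed as a parameter.

## What the synthetic data emulates

The generator plants ground truth for every downstream stage under one
root seed, with independent derived streams per generator so call order
does not matter:

* **ChIP signal** — one synthetic chromosome; peaks of 1-6 kb (straddling
  the 2 kb filter cutoff on purpose) spaced at twice the stitching
  distance (a configurable fraction closer, to exercise stitching);
  condition-1 peak intensity 2000 arbitrary units, background 5% of that;
  condition-2 multiplied by 2.0 (up), 0.5 (down) or 1 (common);
  multiplicative lognormal noise, CV 0.15, mean exactly 1 so the noiseless
  limit reproduces the planted fold changes exactly. One gene per region
  at a known TSS offset within 10 kb gives the distance annotation planted
  truth (offsets stay below half the minimum inter-peak gap so each
  region's nearest TSS is its own gene).
* **Variants** — homogeneous Poisson background at 0.5/kb in both
  conditions; inside up-class regions of condition 2 the rate is 1.5/kb.
* **Screen** — 1139 genes, 6485 guides spread 5-6 per gene; pool counts
  negative binomial (dispersion 0.1) around 500 reads; day-14 counts drift
  per guide (lognormal CV 0.1, shared between arms as a passage effect);
  guides of 4 planted genes are multiplied by 0.2 in the cisplatin arm
  only.
* **Expression panel** — 18 lines, 11 resistant / 7 sensitive; signature
  genes (50 up, 50 down of 500) shifted by +-1 log2 unit in resistant
  lines; GI50 drawn from disjoint ranges (25-60 vs 2-15 uM) so the 20 uM
  threshold reproduces the planted status exactly.

Noise shapes (lognormal for coverage, negative binomial for counts) are the
standard choices for these data types. What the simulation does *not*
contain: real genome sequence, mappability or GC structure, copy-number
aberrations, replicate structure for ChIP (exposed as a parameter but the
reference design is one track per condition), batch effects, or correlated
signatures. Passing the planted-truth tests therefore demonstrates that
the implementation recovers the effects it models under realistic noise —
not that those effects are identifiable in any real dataset, where the
confounders above dominate.

## Problem sizes and tolerances in the test suite

Oracle-agreement tests run at 1e-12 on matrices around 10 x 5 and region
sets of 100-1000; planted-truth recovery runs at the default study
conditions (300 regions, 6485 guides, 18-line panel); calibration uses 100
seeds for detection/power rates and 500 simulated datasets for null
type-I rates, with acceptance bounds of 95% power and 6% type I at nominal
5%. The end-to-end determinism check runs the full pipeline twice at a
reduced region and library count and compares MD5 checksums of every
output file. These sizes keep the whole suite in the low minutes on one
CPU while leaving each statistical bound comfortably powered.

## Known limitations

* The threshold filter is not a statistical test: no replicate variance
  model, no FDR on region calls. That is faithful to the analysis the
  package implements; count-based differential testing is out of scope.
* Hypergeometric enrichment carries the locus-length bias described above.
* The combined gene score, resistance index and screen hit rule are
  reconstructions with the stated defaults; all are pluggable.
* bigWig tracks are not parsed; convert to bedGraph upstream. bedGraph
  intervals must not overlap within a chromosome.
* `read_vcf_positions()` keeps `PASS` and `.` records by default; upstream
  variant-quality filtering is the caller's responsibility (the filter set
  is configurable).
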