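---
title: "Methods: differential histone-methylation analysis from tiling arrays"
author: "tilemark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential histone-methylation analysis from tiling arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tilemark)
```

## The analysis problem

ChIP-chip tiling arrays measure, for every ~220 bp probe along a genome,
the log2 ratio M = log2(IP/input) of immunoprecipitated over input
signal. For a repressive chromatin mark such as H3K27me3, enrichment
appears as broad domains of elevated M covering whole gene bodies.
Comparing two tissues (here called meristem, `Me`, and leaf, `Le`; two
biological replicates each) asks three questions that this package
answers in sequence:

1. **Where are the enriched domains in each hybridisation?**
   (`callDomains()`)
2. **How methylated is each annotated gene, on a comparable scale
   across samples and tissues?** (`methylationScores()`)
3. **Which genes are tissue-specifically methylated, and how does that
   relate to tissue-specific expression and to gene-family membership?**
   (`classifyMethylation()`, `classifyExpression()`,
   `crosstabExpressionMethylation()`, `familyTargetSummary()`,
   `smallRNACoupling()`)

## Domain calling

Each sample's M track is smoothed with a **running median** over a
window of total width `windowBp` (default 1400 bp): the smoothed value
at a probe is the median of raw M over all probes on the same
chromosome whose midpoints lie within `windowBp/2` of its midpoint. The
window is defined by genomic distance, not probe count, so irregular
tiling is handled naturally; an isolated probe keeps its raw value.

A per-sample **intensity threshold** is the 80th percentile
(`thresholdPercentile`) of that sample's genome-wide smoothed
distribution, using the linear-interpolation percentile definition
(type 7). We threshold each hybridisation independently rather than
pooling replicates: each array has its own dynamic range, and replicate
agreement is enforced later at the score level. The scope of the
threshold is recorded in the run manifest.

Probes at or above the threshold (ties included — a deterministic rule)
are chained into **clusters** while the midpoint gap between
consecutive above-threshold probes is at most `maxGapBp` (default
700 bp, half the smoothing window); intervening below-threshold probes
do not break a chain but are not counted in `n_probes`. A cluster spans
from its first to its last probe.

## Methylation scores

The per-annotation score for one sample is the **sum of smoothed M over
above-threshold probes that lie in a called cluster and overlap the
annotation body by at least 1 bp**. The exact aggregation rule is a
genuinely open design choice (probe sum, overlap length and cluster
mean are all defensible); the probe-sum was chosen because it grows
with both domain intensity and domain coverage of the gene, and the
rule's name is recorded in every `MethylationScores` object so
alternative conventions remain comparable. A `flank` argument exposes
body-plus-flank scoring; the default is gene body only.

Each sample column is scaled so its maximum is 100, making replicate
columns comparable without assuming equal precipitation efficiency.
Per-tissue combined scores are replicate means. A **between-tissue
scale normalisation** then divides the non-reference tissue's scores by
the median ratio ms(other)/ms(reference) over genes scored positive in
both tissues — a robust, direction-preserving correction for
differential ChIP efficiency; the factor is recorded and re-application
is a no-op.

A gene is a **target** of a tissue when its score is positive in *both*
replicates of that tissue — the replicate-intersection rule that
substitutes for a formal FDR at n = 2.

## Classification rules

With two replicates per tissue, classification combines magnitude
filters with an equal-variance two-sample Student t-test on the
replicate scores (df = 2; low power is inherent to the design and is
why the magnitude filters carry most of the specificity):

* **dM+** (meristem-specific): Me target, ratio ms(Me)/ms(Le) ≥ 2 *or*
  ms(Le) = 0, t-test p ≤ 0.05, and |ms(Me) − ms(Le)| ≥ 10.
  **dL+** is symmetric.
* **M = L** (equal): target in both tissues, 0.5 < ratio < 2,
  |diff| < 10, and replicate relative SD (SD/mean, per tissue) ≤ 5%.
  The relative-SD reading of the "standard deviation ≤ 0.05" criterion
  is a configurable parameter (`relSDCut`), not hard-coded: a literal
  0.05 score-unit (or 0.05%) ceiling would empty the class on any
  realistic replicate noise.
* Targets meeting neither rule are labelled **target_other** rather
  than silently dropped, so the partition is auditable; non-targets are
  **non_target**.
* Degenerate case: when both replicate groups have zero variance the
  t-statistic is undefined; the significance criterion is then treated
  as met exactly when the magnitude criterion |diff| ≥ 10 holds. This
  keeps the rule deterministic for the common ms(Le) = (0, 0) case.

Expression uses the same pattern on log2 intensities: tissue-specific
bins need |Δlog2(Me − Le)| ≥ 2 *and* t-test p ≤ 0.05; the equal bin
needs |Δlog2| < 1 and the relative-SD criterion; intermediate bins
(1 ≤ |Δlog2| < 2) are kept for the cross-tabulation; genes below a
detection threshold (`detectionThreshold`, default 7 on the log2
intensity scale used by the simulator) in both tissues are
`not_expressed`. Finer sub-bins beyond these boundaries are not built
in; the cross-tabulation operates on whatever labelling it is given,
so custom binnings can be supplied directly.

No multiple-testing correction is applied by default: the per-gene
p ≤ 0.05 filter acts jointly with the magnitude cutoffs, and the t-test
is computed on scores (not log scores or probe-level values) — both
choices are documented conventions of this implementation.

## Enrichment statistics

Fold enrichment of a category within a gene set is the category's
frequency in the set divided by its background frequency. Family
significance uses a 1-df goodness-of-fit chi-square against the
genome-wide frequency (no continuity correction by default, with a
Yates flag for sensitivity checks); term enrichment uses the upper-tail
hypergeometric test. Printed percentages are rounded **half away from
zero** at the table's precision (one decimal for family tables, integer
for coupling totals), which is what reproduces published-style table
values exactly; percentages are always recomputed from counts, never
stored.

## The synthetic study

`simulateTilingData()` generates the study conditions every recovery
test runs under: 4 chromosomes of 1.1 Mb, probes every 220 bp (20 000
probes), 800 non-overlapping genes of 1–3 kb, class fractions
{shared 0.30, meristem-only 0.15, leaf-only 0.25, unmethylated 0.30},
planted enrichment `domainDelta` = 2 M-units over gene bodies with
replicate noise `noiseSd` = 0.5 (i.e. a 4-sigma planted effect), and
log2 expression regimes of 10 (expressed) versus 6 (repressed, below
the detection threshold) with replicate SD 0.15, coupled so that
planted methylation in a tissue suppresses that tissue's expression.
The 4 log2-unit separation makes the |Δlog2| ≥ 2 rule recoverable by
construction; the class fractions keep the per-tissue enriched fraction
near 16% of probes, below the 20% implied by the 80th-percentile
threshold. One master seed drives a named sub-stream per output table,
so each stage is individually reproducible.

What the simulator deliberately does **not** model: dye bias, spatial
array artifacts, probe GC effects, partial-gene or flanking domains,
copy-number variation, and heavy-tailed probe noise. Passing recovery
tests therefore demonstrate the correctness of the algorithmic chain
under idealised Gaussian noise — not performance on real arrays, where
threshold choice and normalisation carry real uncertainty.

## Numerical choices and degenerate inputs

* Percentile: linear interpolation between order statistics (type 7),
  recorded in output metadata.
* Ties at the threshold are included (≥).
* All-zero score columns are returned unscaled with a warning; an
  absent co-positive set makes between-tissue normalisation an error
  that instructs to skip it explicitly.
* "Not detectable" qPCR inputs propagate as `NA`, never as zero.
* Constant columns yield `NA` Spearman coefficients, reported as such.
* Coordinates are 1-based closed (`GRanges`) internally; GFF3 in, BED
  out, with conversions delegated to rtracklayer.

## Problem sizes

The default synthetic study (20 000 probes × 4 samples, 800 genes)
runs the full pipeline in a few seconds; oracle-equivalence suites use
1000 random tracks of ≤ 50 probes. These sizes were chosen so the
complete validation suite exercises every stage at realistic tiling
density while remaining quick to run interactively.

## Limitations

* Two tissues and two replicates are assumed throughout
  classification; more replicates extend the t-test naturally but the
  rules were designed for n = 2.
* The score aggregation rule is a convention; cluster-mean or
  length-weighted variants would shift absolute scores (the recorded
  formula name is there to keep runs comparable).
* Fold enrichment is undefined for empty sets or absent categories and
  is reported as `NA` with a note, not coerced.
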