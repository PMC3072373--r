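# tilemark

Differential histone-methylation analysis for ChIP-chip tiling arrays.

Tiling arrays measure, for every probe, M = log2(IP/input) — the
enrichment of immunoprecipitated chromatin (e.g. H3K27me3-marked) over
input DNA. Comparing two tissues with replicated hybridisations,
`tilemark` answers: where are the methylation domains, how methylated
is each annotated gene, which genes are tissue-specifically methylated,
and how does that couple to tissue-specific expression and to gene
families?

The pipeline:

1. **Domain calling** — running-median smoothing (1400 bp window), a
   per-sample 80th-percentile threshold of the smoothed distribution,
   and chaining of above-threshold probes with a 700 bp distance
   cutoff into clusters.
2. **Methylation scores** — per annotation and sample,
   ms = Σ smoothed M over in-cluster probes overlapping the gene body,
   scaled so each sample column maxes at 100, with median-of-ratios
   scale normalisation between tissues and replicate-intersection
   target calling (ms > 0 in both replicates).
3. **Classification** — meristem-specific (dM+: ratio ≥ 2 or
   ms(Le) = 0, t-test p ≤ 0.05, |diff| ≥ 10), leaf-specific (dL+,
   symmetric), equal (M = L: 0.5 < ratio < 2, |diff| < 10, replicate
   relative SD ≤ 5%), plus the analogous Δlog2-based expression bins
   (dXM ≥ 2, dXL ≤ −2, X(M = L)).
4. **Enrichment statistics** — fold enrichment
   (set frequency / genome frequency), 1-df chi-square family tests,
   upper-tail hypergeometric term tests, per-family target summaries
   and small-RNA/target-gene coupling tables, and the expression ×
   methylation cross-tabulation.

A synthetic-data generator (`simulateTilingData()`) plants methylation
domains and anti-correlated expression with known ground truth, so the
entire chain is testable without array downloads.

## Worked example

```r
library(tilemark)

cfg  <- simulationConfig(nChromosomes = 2, chromLengthBp = 3e5,
                         nGenes = 120, seed = 42)
sim  <- simulateTilingData(cfg)
calls <- callDomains(sim$probes)
calls
#> DomainCalls: 4 samples
#>   clusters per sample: Me_rep1=51, Me_rep2=51, Le_rep1=61, Le_rep2=61
#>   window 1400 bp, max gap 700 bp, percentile 80 (per sample)

ms <- methylationScores(sim$annotations, calls)
ms
#> MethylationScores: 120 annotations, tissues Me/Le
#>   Me targets: 54
#>   Le targets: 64
#>   raw-score rule: sum of smoothed M over in-cluster probes
#>   overlapping the annotation; normalisation factor: 0.9846

mc <- classifyMethylation(ms)
table(mc$label)
#>      dL_plus      dM_plus       M_eq_L   non_target target_other
#>           26           18            1           38           37
```

Each sample yields ~50–60 clusters; 54 and 64 genes are Me and Le
targets (positive score in both replicates), the normalisation factor
0.98 says the two tissues' score scales almost agree, and the
classifier recovers the planted design: all 18 genes planted as
meristem-only methylated are labelled `dM_plus` (100% recovery on this
seed), while shared-methylated genes land in `M_eq_L`/`target_other`,
never in a differential class.

Family summaries reproduce printed-table arithmetic exactly:

```r
familyTargetSummary(list(YUCCAs = paste0("g", 1:34)), paste0("g", 1:23))
#>   family n_total n_target percent_target
#> 1 YUCCAs      34       23           67.6
```

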