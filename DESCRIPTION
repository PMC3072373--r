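Package: tilemark
Title: Differential Histone-Methylation Domain Calling and Scoring from
    Tiling Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calls H3K27me3-enriched domains from ChIP-chip tiling-array
    log-ratio tracks (running-median smoothing, percentile thresholding,
    gap-limited cluster chaining), converts domains into per-annotation
    methylation scores with replicate-intersection target calling and
    between-tissue scale normalisation, classifies genes into
    tissue-specific, equal-methylation and expression classes, and
    computes fold-enrichment, chi-square and hypergeometric statistics
    for gene families, GO-like term sets and miRNA-target coupling.
    Includes a synthetic tiling-array generator with planted methylation
    domains and anti-correlated expression for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
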