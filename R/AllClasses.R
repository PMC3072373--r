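#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom GenomicRanges GRanges GRangesList seqnames start end width
#'   findOverlaps granges sort start<- end<-
#' @importFrom IRanges IRanges overlapsAny
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assays<- rowRanges colData assayNames
NULL

#' Configuration for the synthetic tiling-array generator
#'
#' Holds every knob of the simulated study design: a toy multi-chromosome
#' genome tiled by fixed-spacing probes, a set of non-overlapping genes
#' partitioned into methylation classes (methylated in both tissues, in the
#' meristem only, in the leaf only, or unmethylated), planted M-value
#' enrichment over methylated gene bodies, replicate noise, and optional
#' coupling of planted methylation to suppressed expression in the same
#' tissue.
#'
#' @slot nChromosomes number of chromosomes.
#' @slot chromLengthBp length of each chromosome in bp.
#' @slot probeSpacingBp distance between probe start positions (default
#'   220 bp, the approximate tiling density of the emulated array).
#' @slot probeLengthBp probe length in bp.
#' @slot nGenes total number of simulated genes.
#' @slot geneLengthBp length-2 numeric, min/max gene length (uniform draw).
#' @slot classFractions named numeric over
#'   `c("shared_methylated","meristem_only","leaf_only","unmethylated")`,
#'   must sum to 1.
#' @slot domainDelta mean M-value added inside a planted domain.
#' @slot noiseSd replicate noise SD on the M scale.
#' @slot exprHigh,exprLow log2 expression means for the expressed and
#'   repressed regimes (kept >= 4 log2 units apart by default so the
#'   |delta-log2| >= 2 differential-expression rule is recoverable).
#' @slot exprNoiseSd replicate noise SD on the log2 expression scale.
#' @slot expressionCoupling if `TRUE`, planted methylation in a tissue
#'   draws that tissue's expression from the low regime.
#' @slot tissues length-2 character, tissue labels (reference tissue first).
#' @slot nReplicates replicates per tissue.
#' @slot seed integer master seed; each output table uses a named
#'   sub-stream derived from it.
#' @export
setClass("SimulationConfig",
  representation(
    nChromosomes = "numeric", chromLengthBp = "numeric",
    probeSpacingBp = "numeric", probeLengthBp = "numeric",
    nGenes = "numeric", geneLengthBp = "numeric",
    classFractions = "numeric", domainDelta = "numeric",
    noiseSd = "numeric", exprHigh = "numeric", exprLow = "numeric",
    exprNoiseSd = "numeric", expressionCoupling = "logical",
    tissues = "character", nReplicates = "numeric", seed = "numeric"
  )
)

.SIM_CLASSES <- c("shared_methylated", "meristem_only", "leaf_only",
                  "unmethylated")

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@probeSpacingBp <= 0) msg <- c(msg, "probeSpacingBp must be > 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@domainDelta < 0) msg <- c(msg, "domainDelta must be >= 0")
  cf <- object@classFractions
  if (!setequal(names(cf), .SIM_CLASSES))
    msg <- c(msg, "classFractions must be named over the four gene classes")
  if (abs(sum(cf) - 1) > 1e-9)
    msg <- c(msg, "classFractions must sum to 1")
  if (length(object@tissues) != 2L)
    msg <- c(msg, "exactly two tissues are supported")
  if (length(object@geneLengthBp) != 2L ||
      object@geneLengthBp[1] > object@geneLengthBp[2])
    msg <- c(msg, "geneLengthBp must be c(min, max)")
  if (length(msg)) msg else TRUE
})

#' @rdname SimulationConfig-class
#' @param nChromosomes,chromLengthBp,probeSpacingBp,probeLengthBp,nGenes,geneLengthBp,classFractions,domainDelta,noiseSd,exprHigh,exprLow,exprNoiseSd,expressionCoupling,tissues,nReplicates,seed see slots.
#' @return A validated `SimulationConfig`.
#' @examples
#' cfg <- simulationConfig(nGenes = 50, seed = 1)
#' @export
simulationConfig <- function(nChromosomes = 4, chromLengthBp = 1.1e6,
                             probeSpacingBp = 220, probeLengthBp = 50,
                             nGenes = 800, geneLengthBp = c(1000, 3000),
                             classFractions = c(shared_methylated = 0.3,
                                                meristem_only = 0.15,
                                                leaf_only = 0.25,
                                                unmethylated = 0.3),
                             domainDelta = 2, noiseSd = 0.5,
                             exprHigh = 10, exprLow = 6,
                             exprNoiseSd = 0.15,
                             expressionCoupling = TRUE,
                             tissues = c("Me", "Le"), nReplicates = 2,
                             seed = 1L) {
  new("SimulationConfig", nChromosomes = nChromosomes,
      chromLengthBp = chromLengthBp, probeSpacingBp = probeSpacingBp,
      probeLengthBp = probeLengthBp, nGenes = nGenes,
      geneLengthBp = geneLengthBp, classFractions = classFractions,
      domainDelta = domainDelta, noiseSd = noiseSd, exprHigh = exprHigh,
      exprLow = exprLow, exprNoiseSd = exprNoiseSd,
      expressionCoupling = expressionCoupling, tissues = tissues,
      nReplicates = nReplicates, seed = seed)
}

#' Tiling-probe track with per-sample M-values
#'
#' A thin wrapper around [SummarizedExperiment::RangedSummarizedExperiment]
#' whose rows are tiling probes (a `GRanges`), whose columns are
#' hybridisations (tissue x replicate, recorded in `colData`), and whose
#' `"M"` assay holds the per-probe log2(IP/input) ratios. A `"smoothed"`
#' assay is added by [smoothRunningMedian()].
#'
#' @export
setClass("ProbeTrack", contains = "RangedSummarizedExperiment")

setValidity("ProbeTrack", function(object) {
  msg <- character()
  if (!"M" %in% assayNames(object))
    msg <- c(msg, "assay 'M' is required")
  cd <- colData(object)
  if (!all(c("tissue", "replicate") %in% colnames(cd)))
    msg <- c(msg, "colData must have 'tissue' and 'replicate'")
  if (any(start(rowRanges(object)) > end(rowRanges(object))))
    msg <- c(msg, "probe start must be <= end")
  if (length(msg)) msg else TRUE
})

#' @rdname ProbeTrack-class
#' @param probes `GRanges` of probe intervals (sorted per chromosome).
#' @param M numeric matrix, probes x samples, of log2(IP/input) values.
#' @param tissue,replicate per-column sample labels.
#' @return A `ProbeTrack`.
#' @export
ProbeTrack <- function(probes, M, tissue, replicate) {
  M <- as.matrix(M)
  colnames(M) <- paste0(tissue, "_rep", replicate)
  se <- SummarizedExperiment(
    assays = list(M = M), rowRanges = probes,
    colData = DataFrame(tissue = tissue, replicate = replicate,
                        row.names = colnames(M)))
  new("ProbeTrack", se)
}

#' Per-sample methylation clusters with their thresholds
#'
#' Result container of [callDomains()]: one `GRanges` of clusters per
#' hybridisation, the per-sample smoothed-intensity thresholds, and the
#' calling parameters. Cluster ranges carry `n_probes` (above-threshold
#' probes chained), `mean_smoothed_M` and `tissue`/`replicate` labels.
#'
#' @slot clusters `GRangesList`, one element per sample.
#' @slot thresholds named numeric, one threshold per sample.
#' @slot params the parameter list used (window, gap, percentile).
#' @export
setClass("DomainCalls",
  representation(clusters = "GRangesList", thresholds = "numeric",
                 params = "list"))

#' @describeIn DomainCalls-class cluster list accessor
#' @param x,object a `DomainCalls`.
#' @export
clusters <- function(x) x@clusters

#' @describeIn DomainCalls-class per-sample threshold accessor
#' @export
thresholds <- function(x) x@thresholds

setMethod("show", "DomainCalls", function(object) {
  cat("DomainCalls:", length(object@clusters), "samples\n")
  n <- vapply(object@clusters, length, integer(1))
  cat("  clusters per sample:", paste(names(n), n, sep = "=",
                                      collapse = ", "), "\n")
  cat(sprintf("  window %g bp, max gap %g bp, percentile %g (per sample)\n",
              object@params$windowBp, object@params$maxGapBp,
              object@params$thresholdPercentile))
})

#' Per-annotation methylation score table
#'
#' Holds replicate-level methylation scores ms per annotation and sample
#' (scaled so each sample column has maximum 100), the per-tissue combined
#' scores (replicate means, leaf rescaled by the between-tissue
#' normalisation factor when applied), and the replicate-intersection
#' target flags.
#'
#' @slot scores `DataFrame` with one row per annotation: replicate columns
#'   `ms_<tissue>_rep<k>`, combined `ms_<tissue>`, and logical
#'   `target_<tissue>` flags.
#' @slot tissues the two tissue labels (reference first).
#' @slot normFactor between-tissue scale-normalisation factor applied to
#'   the non-reference tissue (`NA` before normalisation).
#' @slot scoreFormula name of the raw-score rule, recorded so alternative
#'   scoring conventions stay comparable.
#' @export
setClass("MethylationScores",
  representation(scores = "DataFrame", tissues = "character",
                 normFactor = "numeric", scoreFormula = "character"))

setValidity("MethylationScores", function(object) {
  sc <- object@scores
  repc <- grep("^ms_.*_rep", colnames(sc), value = TRUE)
  if (any(vapply(repc, function(cn) any(sc[[cn]] < 0), logical(1))))
    return("methylation scores must be non-negative")
  TRUE
})

#' @describeIn MethylationScores-class the score `DataFrame`
#' @param x,object a `MethylationScores`.
#' @export
scoreTable <- function(x) x@scores

#' @describeIn MethylationScores-class between-tissue normalisation factor
#' @export
normFactor <- function(x) x@normFactor

setMethod("show", "MethylationScores", function(object) {
  sc <- object@scores
  cat("MethylationScores:", nrow(sc), "annotations,",
      "tissues", paste(object@tissues, collapse = "/"), "\n")
  for (ti in object@tissues)
    cat(sprintf("  %s targets: %d\n", ti, sum(sc[[paste0("target_", ti)]])))
  cat(sprintf("  raw-score rule: %s; normalisation factor: %s\n",
              object@scoreFormula,
              ifelse(is.na(object@normFactor), "not applied",
                     format(object@normFactor, digits = 4))))
})
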