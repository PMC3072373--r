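#' Simulate a tiling-array methylation study with known ground truth
#'
#' Generates a toy genome tiled by fixed-spacing probes, places
#' non-overlapping genes, assigns each gene a planted methylation class,
#' and draws replicate M-value tracks for two tissues: background probes
#' are Normal(0, noiseSd), probes overlapping a tissue's planted domains
#' are Normal(domainDelta, noiseSd). Planted domains span the full gene
#' body. Matched log2 expression intensities are drawn per tissue and
#' replicate; with `expressionCoupling` on, a gene methylated in a tissue
#' is drawn from the low-expression regime in that tissue, giving the
#' anti-correlated structure the downstream cross-tabulation is designed
#' to detect.
#'
#' All randomness flows from `config@seed` through named per-table
#' sub-streams, so identical configurations reproduce identical outputs
#' table by table.
#'
#' @param config a [SimulationConfig-class].
#' @return a list with elements:
#'   \describe{
#'     \item{annotations}{`GRanges` of genes with `ID` and `category`.}
#'     \item{probes}{a [ProbeTrack-class] with the `"M"` assay.}
#'     \item{expression}{data.frame `gene_id` plus
#'       `log2_<tissue>_rep<k>` columns.}
#'     \item{truth}{data.frame of planted class, coordinates and planted
#'       expression means per gene.}
#'     \item{domains}{named list of `GRanges`, planted domains per tissue.}
#'   }
#' @examples
#' sim <- simulateTilingData(simulationConfig(nChromosomes = 1,
#'   chromLengthBp = 5e4, nGenes = 10, seed = 7))
#' @export
simulateTilingData <- function(config) {
  validObject(config)
  nprobe_chr <- floor((config@chromLengthBp - config@probeLengthBp) /
                        config@probeSpacingBp) + 1
  if (nprobe_chr < 1)
    stop("chromosome length yields zero probes per chromosome")
  chroms <- paste0("chr", seq_len(config@nChromosomes))

  probes <- GRanges(
    rep(chroms, each = nprobe_chr),
    IRanges(start = rep(seq(1, by = config@probeSpacingBp,
                            length.out = nprobe_chr),
                        times = config@nChromosomes),
            width = config@probeLengthBp))
  names(probes) <- paste0("probe_", seq_along(probes))

  genes <- .placeGenes(config, chroms)
  classes <- .assignClasses(config)
  mcols(genes)$class <- classes

  dom <- list()
  dom[[config@tissues[1]]] <-
    granges(genes[classes %in% c("shared_methylated", "meristem_only")])
  dom[[config@tissues[2]]] <-
    granges(genes[classes %in% c("shared_methylated", "leaf_only")])

  sampTissue <- rep(config@tissues, each = config@nReplicates)
  sampRep <- rep(seq_len(config@nReplicates), times = 2)
  M <- matrix(0, nrow = length(probes), ncol = length(sampTissue))
  for (j in seq_along(sampTissue)) {
    set.seed(.subSeed(config@seed,
                      paste0("probes_", sampTissue[j], "_", sampRep[j])))
    mu <- ifelse(overlapsAny(probes, dom[[sampTissue[j]]]),
                 config@domainDelta, 0)
    M[, j] <- stats::rnorm(length(probes), mean = mu, sd = config@noiseSd)
  }
  track <- ProbeTrack(probes, M, sampTissue, sampRep)

  expr <- .simulateExpression(config, genes, classes)

  truth <- data.frame(
    gene_id = names(genes),
    class = classes,
    chrom = as.character(seqnames(genes)),
    start = start(genes), end = end(genes),
    expr_mean_Me = expr$means[, 1], expr_mean_Le = expr$means[, 2],
    stringsAsFactors = FALSE)
  names(truth)[6:7] <- paste0("expr_mean_", config@tissues)

  list(annotations = genes, probes = track, expression = expr$table,
       truth = truth, domains = dom)
}

# Place nGenes non-overlapping genes: lengths uniform in the configured
# range, intergenic gaps drawn then rescaled so every chromosome's genes
# fit exactly within its length. Guarantees disjoint planted domains.
.placeGenes <- function(config, chroms) {
  set.seed(.subSeed(config@seed, "genes"))
  perChrom <- rep(floor(config@nGenes / config@nChromosomes),
                  config@nChromosomes)
  extra <- config@nGenes - sum(perChrom)
  if (extra > 0) perChrom[seq_len(extra)] <- perChrom[seq_len(extra)] + 1
  grl <- vector("list", config@nChromosomes)
  for (ci in seq_len(config@nChromosomes)) {
    n <- perChrom[ci]
    if (n == 0L) { grl[[ci]] <- GRanges(); next }
    len <- round(stats::runif(n, config@geneLengthBp[1],
                              config@geneLengthBp[2]))
    slack <- config@chromLengthBp - sum(len)
    if (slack < n + 1)
      stop("genes do not fit on chromosome; reduce nGenes or gene length")
    gw <- stats::runif(n + 1)
    gaps <- floor(gw / sum(gw) * slack)
    st <- cumsum(gaps[seq_len(n)] + c(0, len[-n])) + 1
    grl[[ci]] <- GRanges(chroms[ci], IRanges(start = st, width = len))
  }
  genes <- suppressWarnings(do.call(c, grl))
  names(genes) <- sprintf("GENE%04d", seq_along(genes))
  mcols(genes)$ID <- names(genes)
  mcols(genes)$category <- "protein_coding"
  genes
}

# Deterministic class counts from the fractions (largest-remainder), then
# a seeded shuffle over genes. The labels partition the gene set.
.assignClasses <- function(config) {
  cf <- config@classFractions[.SIM_CLASSES]
  n <- config@nGenes
  cnt <- floor(cf * n)
  rem <- n - sum(cnt)
  if (rem > 0) {
    ord <- order(cf * n - cnt, decreasing = TRUE)
    cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
  }
  set.seed(.subSeed(config@seed, "classes"))
  sample(rep(.SIM_CLASSES, times = cnt))
}

.simulateExpression <- function(config, genes, classes) {
  n <- length(genes)
  means <- matrix(config@exprHigh, nrow = n, ncol = 2,
                  dimnames = list(names(genes), config@tissues))
  if (config@expressionCoupling) {
    means[classes %in% c("shared_methylated", "meristem_only"), 1] <-
      config@exprLow
    means[classes %in% c("shared_methylated", "leaf_only"), 2] <-
      config@exprLow
  }
  tab <- data.frame(gene_id = names(genes), stringsAsFactors = FALSE)
  for (ti in seq_along(config@tissues)) {
    for (r in seq_len(config@nReplicates)) {
      set.seed(.subSeed(config@seed,
                        paste0("expr_", config@tissues[ti], "_", r)))
      tab[[paste0("log2_", config@tissues[ti], "_rep", r)]] <-
        stats::rnorm(n, mean = means[, ti], sd = config@exprNoiseSd)
    }
  }
  list(table = tab, means = means)
}

#' Write a simulated dataset to disk in the package's exchange formats
#'
#' Annotations go out as GFF3, probe tracks as one TSV
#' (chrom, start, end, M; 1-based inclusive coordinates) per
#' tissue x replicate, expression and truth as TSV.
#'
#' @param sim result of [simulateTilingData()].
#' @param outdir output directory (created if absent).
#' @return invisibly, a named character vector of the files written.
#' @export
writeSimulatedData <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- c(annotations = file.path(outdir, "annotations.gff3"))
  writeAnnotations(sim$annotations, files[["annotations"]])
  cd <- colData(sim$probes)
  M <- assay(sim$probes, "M")
  gr <- rowRanges(sim$probes)
  for (j in seq_len(ncol(sim$probes))) {
    key <- paste0("probes_", cd$tissue[j], "_rep", cd$replicate[j])
    f <- file.path(outdir, paste0(key, ".tsv"))
    utils::write.table(
      data.frame(chrom = as.character(seqnames(gr)), start = start(gr),
                 end = end(gr),
                 M = sprintf("%.17g", M[, j])),  # lossless round-trip
      f, sep = "\t", quote = FALSE, row.names = FALSE)
    files[[key]] <- f
  }
  expr_out <- sim$expression
  for (cn in names(expr_out))
    if (is.numeric(expr_out[[cn]]))
      expr_out[[cn]] <- sprintf("%.17g", expr_out[[cn]])
  files[["expression"]] <- file.path(outdir, "expression.tsv")
  utils::write.table(expr_out, files[["expression"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files[["truth"]] <- file.path(outdir, "truth.tsv")
  utils::write.table(sim$truth, files[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(files)
}
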