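#' Assemble a pipeline configuration
#'
#' A single configuration object drives a full reproducible run:
#' simulation settings (or paths to existing inputs), domain-calling
#' parameters, classification thresholds, normalisation toggle and the
#' master seed. Can also be loaded from a YAML file with
#' [readPipelineConfig()]; the realised configuration is mirrored into
#' the run manifest.
#'
#' @param sim a [SimulationConfig-class], or `NULL` to read existing
#'   inputs from `paths`.
#' @param paths named list of input files (`annotations`, `probes` =
#'   named character vector per sample, `expression`) when `sim` is
#'   `NULL`.
#' @param windowBp,maxGapBp,thresholdPercentile domain-calling
#'   parameters.
#' @param alpha,ratioCut,diffCut,relSDCut methylation-classification
#'   thresholds.
#' @param diffCutLog2,equalCutLog2,detectionThreshold expression-binning
#'   thresholds.
#' @param normalize apply between-tissue score normalisation.
#' @param referenceTissue tissue held fixed by the normalisation
#'   (default `NULL`: the first tissue encountered in the track).
#' @param seed master seed (also forwarded into `sim`).
#' @return a list of class `"tilemark_config"`.
#' @export
pipelineConfig <- function(sim = simulationConfig(), paths = NULL,
                           windowBp = 1400, maxGapBp = 700,
                           thresholdPercentile = 80, alpha = 0.05,
                           ratioCut = 2, diffCut = 10, relSDCut = 0.05,
                           diffCutLog2 = 2, equalCutLog2 = 1,
                           detectionThreshold = 7, normalize = TRUE,
                           referenceTissue = NULL, seed = 1L) {
  if (!is.null(sim)) sim@seed <- as.numeric(seed)
  structure(list(sim = sim, paths = paths, windowBp = windowBp,
                 maxGapBp = maxGapBp,
                 thresholdPercentile = thresholdPercentile,
                 alpha = alpha, ratioCut = ratioCut, diffCut = diffCut,
                 relSDCut = relSDCut, diffCutLog2 = diffCutLog2,
                 equalCutLog2 = equalCutLog2,
                 detectionThreshold = detectionThreshold,
                 normalize = normalize,
                 referenceTissue = referenceTissue, seed = seed),
            class = "tilemark_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised keys mirror the [pipelineConfig()] arguments; `sim` keys
#' mirror [simulationConfig()] (with `classFractions` as a named map).
#'
#' @param path YAML file.
#' @return a `"tilemark_config"` list.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  simArgs <- y$sim
  sim <- if (is.null(simArgs)) NULL else {
    if (!is.null(simArgs$classFractions))
      simArgs$classFractions <- unlist(simArgs$classFractions)
    do.call(simulationConfig, simArgs)
  }
  args <- y[setdiff(names(y), "sim")]
  do.call(pipelineConfig, c(list(sim = sim), args))
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> call-domains -> score -> classify
#' -> enrich into a run directory, writing every stage's output as
#' TSV/BED plus a JSON manifest recording parameters, per-sample
#' thresholds, the normalisation factor, the seed, stage-level counts
#' and md5 checksums of all outputs. Re-running with the same
#' configuration and seed reproduces byte-identical outputs. Any stage
#' failure aborts with the stage name; missing input paths abort before
#' any stage runs.
#'
#' @param config a `"tilemark_config"` from [pipelineConfig()].
#' @param outdir run directory (created).
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config, outdir) {
  stopifnot(inherits(config, "tilemark_config"))
  if (is.null(config$sim)) {
    need <- c(config$paths$annotations, unlist(config$paths$probes),
              config$paths$expression)
    missing <- need[!file.exists(need)]
    if (length(missing))
      stop("input file(s) not found (checked before any stage ran): ",
           paste(missing, collapse = ", "))
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list(),
                   parameters = config[setdiff(names(config),
                                               c("sim", "paths"))])
  outputs <- character()
  stage <- function(name, fn) {
    tryCatch(fn(), error = function(e)
      stop("pipeline stage '", name, "' failed: ",
           conditionMessage(e), call. = FALSE))
  }

  # -- simulate (or load) ---------------------------------------------
  env <- new.env()
  stage("simulate", function() {
    if (!is.null(config$sim)) {
      sim <- simulateTilingData(config$sim)
      files <- writeSimulatedData(sim, file.path(outdir, "input"))
      env$ann <- sim$annotations
      env$track <- sim$probes
      env$expr <- sim$expression
      env$truth <- sim$truth
      outputs <<- c(outputs, files)
      manifest$stages$simulate <<- list(
        n_genes = length(sim$annotations),
        n_probes = nrow(sim$probes))
    } else {
      env$ann <- readAnnotations(config$paths$annotations)
      pr <- config$paths$probes
      lab <- do.call(rbind, strsplit(names(pr), "_rep"))
      env$track <- readProbeTracks(unname(pr), lab[, 1],
                                   as.integer(lab[, 2]))
      env$expr <- utils::read.delim(config$paths$expression,
                                    stringsAsFactors = FALSE)
      manifest$stages$simulate <<- list(
        loaded = TRUE, n_genes = length(env$ann),
        n_probes = nrow(env$track))
    }
  })

  stage("call-domains", function() {
    env$calls <- callDomains(env$track, windowBp = config$windowBp,
                             maxGapBp = config$maxGapBp,
                             thresholdPercentile =
                               config$thresholdPercentile)
    for (s in names(clusters(env$calls))) {
      f <- file.path(outdir, paste0("clusters_", s, ".bed"))
      writeClustersBed(clusters(env$calls)[[s]], f)
      outputs <<- c(outputs, f)
    }
    manifest$stages$call_domains <<- list(
      thresholds = as.list(thresholds(env$calls)),
      threshold_scope = env$calls@params$thresholdScope,
      n_clusters = lapply(clusters(env$calls), length))
  })

  stage("score", function() {
    env$ms <- methylationScores(env$ann, env$calls,
                                normalize = config$normalize,
                                referenceTissue = config$referenceTissue)
    f <- file.path(outdir, "scores.tsv")
    utils::write.table(as.data.frame(scoreTable(env$ms)), f,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <<- c(outputs, f)
    tg <- callTargets(env$ms)
    manifest$stages$score <<- list(
      normalisation_factor = normFactor(env$ms),
      score_formula = env$ms@scoreFormula,
      target_counts = as.list(tg$counts))
  })

  stage("classify", function() {
    mc <- classifyMethylation(env$ms, alpha = config$alpha,
                              ratioCut = config$ratioCut,
                              diffCut = config$diffCut,
                              relSDCut = config$relSDCut)
    eb <- classifyExpression(env$expr,
                             tissues = env$ms@tissues,
                             alpha = config$alpha,
                             diffCutLog2 = config$diffCutLog2,
                             equalCutLog2 = config$equalCutLog2,
                             relSDCut = config$relSDCut,
                             detectionThreshold =
                               config$detectionThreshold)
    env$mc <- mc; env$eb <- eb
    cls <- merge(mc, eb, by.x = "id", by.y = "gene_id", all.x = TRUE)
    cls <- cls[order(cls$id), ]
    f <- file.path(outdir, "classes.tsv")
    utils::write.table(cls, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    outputs <<- c(outputs, f)
    manifest$stages$classify <<- list(
      methylation_counts = as.list(table(mc$label)),
      expression_counts = as.list(table(eb$bin)))
  })

  stage("enrich", function() {
    meth <- stats::setNames(env$mc$label, env$mc$id)
    expr <- stats::setNames(env$eb$bin, env$eb$gene_id)
    ct <- crosstabExpressionMethylation(meth, expr)
    f <- file.path(outdir, "crosstab.tsv")
    utils::write.table(ct, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    outputs <<- c(outputs, f)
    manifest$stages$enrich <<- list(n_cells = nrow(ct))
  })

  manifest$outputs <- as.list(tools::md5sum(sort(unname(outputs))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(manifest)
}
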