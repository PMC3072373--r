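suppressPackageStartupMessages({
  library(GenomicRanges)
  library(SummarizedExperiment)
  library(S4Vectors)
})

# Probe track at given midpoints (width-1 probes so midpoint == start),
# one chromosome, arbitrary sample columns.
tinyTrack <- function(mids, M, chrom = "chr1",
                      tissue = NULL, replicate = NULL) {
  M <- as.matrix(M)
  if (is.null(tissue))
    tissue <- rep(c("Me", "Le"), length.out = ncol(M))
  if (is.null(replicate)) replicate <- seq_len(ncol(M))
  ProbeTrack(GRanges(chrom, IRanges(mids, width = 1)), M,
             tissue, replicate)
}

# Brute-force oracles for the smoothing / threshold / chaining stage.
bruteSmooth <- function(mids, M, windowBp) {
  half <- windowBp / 2
  vapply(seq_along(mids), function(i)
    median(M[abs(mids - mids[i]) <= half]), numeric(1))
}

brutePercentile <- function(x, p) {
  # linear interpolation between order statistics
  x <- sort(x)
  h <- (length(x) - 1) * p / 100 + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

bruteClusters <- function(mids, sm, thr, maxGap) {
  above <- which(sm >= thr)
  if (!length(above)) return(NULL)
  runs <- list(above[1])
  for (i in above[-1]) {
    last <- runs[[length(runs)]]
    if (mids[i] - mids[last[length(last)]] <= maxGap)
      runs[[length(runs)]] <- c(last, i)
    else runs[[length(runs) + 1]] <- i
  }
  do.call(rbind, lapply(runs, function(r)
    data.frame(start = mids[r[1]], end = mids[r[length(r)]],
               n = length(r), mean = mean(sm[r]))))
}

# MethylationScores built straight from replicate matrices, for rule
# tests that do not need the array stage.
scoresFromReps <- function(repMe, repLe, tissues = c("Me", "Le")) {
  repMe <- as.matrix(repMe); repLe <- as.matrix(repLe)
  n <- nrow(repMe)
  ids <- sprintf("g%03d", seq_len(n))
  sc <- DataFrame(row.names = ids)
  sc$id <- ids
  for (k in seq_len(ncol(repMe)))
    sc[[paste0("ms_", tissues[1], "_rep", k)]] <- repMe[, k]
  for (k in seq_len(ncol(repLe)))
    sc[[paste0("ms_", tissues[2], "_rep", k)]] <- repLe[, k]
  sc[[paste0("ms_", tissues[1])]] <- rowMeans(repMe)
  sc[[paste0("ms_", tissues[2])]] <- rowMeans(repLe)
  sc[[paste0("target_", tissues[1])]] <- apply(repMe > 0, 1, all)
  sc[[paste0("target_", tissues[2])]] <- apply(repLe > 0, 1, all)
  new("MethylationScores", scores = sc, tissues = tissues,
      normFactor = NA_real_, scoreFormula = "test fixture")
}

# The full-scale synthetic study used by recovery and acceptance tests;
# computed once per test run.
.fullSim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulateTilingData(simulationConfig(seed = 1))
      calls <- callDomains(sim$probes)
      ms <- methylationScores(sim$annotations, calls)
      cache <<- list(sim = sim, calls = calls, ms = ms,
                     meth = classifyMethylation(ms),
                     expr = classifyExpression(sim$expression))
    }
    cache
  }
})

extfile <- function(f) system.file("extdata", f, package = "tilemark")
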