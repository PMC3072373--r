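#' Smooth probe tracks with a position-based running median
#'
#' The smoothed value at probe i is the median of the raw M values of all
#' probes on the same chromosome whose midpoints lie within
#' `windowBp / 2` of probe i's midpoint; the window always contains probe
#' i itself, so an isolated probe keeps its raw value. The default total
#' window width of 1400 bp spans roughly seven probes at 220 bp tiling.
#'
#' @param track a [ProbeTrack-class].
#' @param windowBp total window width in bp.
#' @return the track with an added `"smoothed"` assay.
#' @export
smoothRunningMedian <- function(track, windowBp = 1400) {
  stopifnot(windowBp > 0)
  M <- assay(track, "M")
  if (nrow(M) == 0) {
    S4Vectors::metadata(track)$windowBp <- windowBp
    assays(track)$smoothed <- M
    return(track)
  }
  gr <- rowRanges(track)
  sm <- matrix(NA_real_, nrow = nrow(M), ncol = ncol(M),
               dimnames = dimnames(M))
  for (chr in unique(as.character(seqnames(gr)))) {
    idx <- which(as.character(seqnames(gr)) == chr)
    mids <- (start(gr)[idx] + end(gr)[idx]) / 2
    o <- order(mids)
    idx <- idx[o]; mids <- mids[o]
    half <- windowBp / 2
    lo <- findInterval(mids - half - 1e-9, mids) + 1L
    hi <- findInterval(mids + half + 1e-9, mids)
    sub <- M[idx, , drop = FALSE]
    for (j in seq_len(ncol(M))) {
      col <- sub[, j]
      sm[idx, j] <- vapply(seq_along(idx), function(i)
        stats::median(col[lo[i]:hi[i]]), numeric(1))
    }
  }
  assays(track)$smoothed <- sm
  S4Vectors::metadata(track)$windowBp <- windowBp
  track
}

#' Percentile threshold of a smoothed intensity distribution
#'
#' Linear-interpolation percentile (the common type-7 definition) of one
#' sample's smoothed values, computed over the whole genome, not per
#' chromosome.
#'
#' @param values numeric vector of smoothed M values for one sample.
#' @param percentile percentile in (0, 100].
#' @return the threshold M value.
#' @examples computeThreshold(1:10, 80)  # 8.2
#' @export
computeThreshold <- function(values, percentile = 80) {
  values <- values[is.finite(values)]
  if (length(values) == 0) stop("no finite values to threshold")
  stopifnot(percentile > 0, percentile <= 100)
  stats::quantile(values, percentile / 100, type = 7, names = FALSE)
}

#' Chain above-threshold probes into methylation clusters
#'
#' Probes whose smoothed value is at or above the threshold (ties
#' included) are chained along each chromosome while the midpoint gap
#' between consecutive above-threshold probes is at most `maxGapBp`;
#' below-threshold probes lying between them do not break the chain. A
#' cluster spans from the start of its first probe to the end of its
#' last.
#'
#' @param probes `GRanges` of probe positions.
#' @param smoothed numeric vector of smoothed M values, parallel to
#'   `probes`.
#' @param threshold intensity threshold (see [computeThreshold()]).
#' @param maxGapBp distance cutoff between consecutive above-threshold
#'   probe midpoints.
#' @return `GRanges` of non-overlapping, sorted clusters with `n_probes`
#'   (above-threshold probes chained) and `mean_smoothed_M` columns;
#'   empty when no probe passes the threshold.
#' @export
callClusters <- function(probes, smoothed, threshold, maxGapBp = 700) {
  stopifnot(length(probes) == length(smoothed), maxGapBp >= 0)
  above <- which(smoothed >= threshold)
  if (length(above) == 0)
    return(GRanges(n_probes = integer(), mean_smoothed_M = numeric()))
  gr <- probes[above]
  val <- smoothed[above]
  chr <- as.character(seqnames(gr))
  mids <- (start(gr) + end(gr)) / 2
  o <- order(chr, mids)
  gr <- gr[o]; val <- val[o]; chr <- chr[o]; mids <- mids[o]
  newrun <- c(TRUE, chr[-1] != chr[-length(chr)] |
                diff(mids) > maxGapBp)
  run <- cumsum(newrun)
  cl <- GRanges(
    vapply(split(chr, run), `[`, character(1), 1),
    IRanges(start = vapply(split(start(gr), run), min, numeric(1)),
            end = vapply(split(end(gr), run), max, numeric(1))))
  mcols(cl)$n_probes <- as.integer(tabulate(run))
  mcols(cl)$mean_smoothed_M <- unname(vapply(split(val, run), mean,
                                             numeric(1)))
  sort(cl)
}

#' Call methylation domains on every sample of a probe track
#'
#' Runs the full domain-calling stage: running-median smoothing, a
#' per-sample percentile threshold of the smoothed distribution (each
#' hybridisation is thresholded independently), and gap-limited cluster
#' chaining.
#'
#' @param track a [ProbeTrack-class].
#' @param windowBp running-median total window width (default 1400 bp).
#' @param maxGapBp cluster distance cutoff (default 700 bp).
#' @param thresholdPercentile percentile of the smoothed distribution
#'   (default 80).
#' @return a [DomainCalls-class]; the smoothed track is attached as the
#'   `"track"` element of its params so downstream scoring reuses it.
#' @export
callDomains <- function(track, windowBp = 1400, maxGapBp = 700,
                        thresholdPercentile = 80) {
  if (!"smoothed" %in% assayNames(track))
    track <- smoothRunningMedian(track, windowBp)
  sm <- assay(track, "smoothed")
  gr <- rowRanges(track)
  thr <- apply(sm, 2, computeThreshold, percentile = thresholdPercentile)
  cl <- lapply(seq_len(ncol(sm)), function(j)
    callClusters(gr, sm[, j], thr[j], maxGapBp))
  names(cl) <- colnames(sm)
  for (j in seq_along(cl)) {
    if (length(cl[[j]])) {
      mcols(cl[[j]])$tissue <- colData(track)$tissue[j]
      mcols(cl[[j]])$replicate <- colData(track)$replicate[j]
    }
  }
  new("DomainCalls", clusters = GRangesList(cl, compress = FALSE),
      thresholds = thr,
      params = list(windowBp = windowBp, maxGapBp = maxGapBp,
                    thresholdPercentile = thresholdPercentile,
                    thresholdScope = "per sample (tissue x replicate)",
                    track = track))
}
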