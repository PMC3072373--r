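#' Raw per-annotation methylation scores for one sample
#'
#' The raw score of an annotation is the sum of smoothed M values over
#' probes that lie inside a called cluster (i.e. are above that sample's
#' threshold within a cluster span) and overlap the annotation interval
#' by at least 1 bp; 0 when no such probe exists. Annotations on
#' chromosomes absent from the track score 0 with a warning.
#'
#' @param annotations annotation `GRanges` (named by id).
#' @param clusters `GRanges` of clusters for the sample.
#' @param probes probe `GRanges`.
#' @param smoothed smoothed M vector for the sample, parallel to
#'   `probes`.
#' @param threshold the sample's calling threshold.
#' @param flank bp added on both sides of each annotation before overlap
#'   (default 0: gene body only).
#' @return numeric vector of raw scores, named by annotation id.
#' @export
scoreAnnotations <- function(annotations, clusters, probes, smoothed,
                             threshold, flank = 0) {
  score <- stats::setNames(numeric(length(annotations)),
                           names(annotations))
  missing_chr <- !(as.character(seqnames(annotations)) %in%
                     unique(as.character(seqnames(probes))))
  if (any(missing_chr))
    warning(sum(missing_chr),
            " annotation(s) on chromosomes absent from the track score 0")
  if (length(clusters) == 0) return(score)
  inCluster <- which(suppressWarnings(overlapsAny(probes, clusters)) &
                       smoothed >= threshold)
  if (length(inCluster) == 0) return(score)
  ann <- annotations
  if (flank > 0) {
    start(ann) <- pmax(1, start(ann) - flank)
    end(ann) <- end(ann) + flank
  }
  # seqlevel mismatches are already reported above as zero-score warnings
  hits <- suppressWarnings(findOverlaps(probes[inCluster], ann,
                                        minoverlap = 1L))
  if (length(hits) == 0) return(score)
  s <- tapply(smoothed[inCluster][S4Vectors::queryHits(hits)],
              S4Vectors::subjectHits(hits), sum)
  score[as.integer(names(s))] <- as.numeric(s)
  score
}

#' Scale a column of raw scores so its maximum is 100
#'
#' @param raw numeric vector of raw scores for one sample.
#' @return scaled vector; an all-zero column is returned unchanged with a
#'   warning; negative input is an error.
#' @examples scaleScores(c(5, 10, 20))  # 25 50 100
#' @export
scaleScores <- function(raw) {
  if (any(raw < 0)) stop("negative raw methylation score")
  mx <- max(raw)
  if (mx == 0) {
    warning("all-zero score column left unscaled")
    return(raw)
  }
  raw * 100 / mx
}

#' Compute the full methylation score table for all samples
#'
#' Scores every annotation in every sample, scales each sample column to
#' maximum 100, averages replicates into per-tissue combined scores,
#' calls per-tissue targets (positive score in both replicates), and
#' optionally applies the between-tissue scale normalisation (see
#' [normalizeBetweenTissues()]).
#'
#' @param annotations annotation `GRanges`.
#' @param calls a [DomainCalls-class] from [callDomains()].
#' @param flank bp of flank around each annotation (default 0).
#' @param normalize apply between-tissue normalisation (default `TRUE`).
#' @param referenceTissue tissue whose scale is held fixed (default the
#'   first tissue in the track's colData).
#' @return a [MethylationScores-class].
#' @export
methylationScores <- function(annotations, calls, flank = 0,
                              normalize = TRUE, referenceTissue = NULL) {
  track <- calls@params$track
  cd <- colData(track)
  probes <- rowRanges(track)
  sm <- assay(track, "smoothed")
  tissues <- unique(cd$tissue)
  stopifnot(length(tissues) == 2)
  if (is.null(referenceTissue)) referenceTissue <- tissues[1]
  tissues <- c(referenceTissue, setdiff(tissues, referenceTissue))

  sc <- DataFrame(row.names = names(annotations))
  sc$id <- names(annotations)
  for (j in seq_len(ncol(track))) {
    raw <- scoreAnnotations(annotations, clusters(calls)[[j]], probes,
                            sm[, j], thresholds(calls)[j], flank = flank)
    sc[[paste0("ms_", cd$tissue[j], "_rep", cd$replicate[j])]] <-
      scaleScores(raw)
  }
  for (ti in tissues) {
    repc <- grep(paste0("^ms_", ti, "_rep"), colnames(sc), value = TRUE)
    stopifnot(length(repc) >= 2)
    sc[[paste0("ms_", ti)]] <- rowMeans(as.matrix(as.data.frame(sc[repc])))
    sc[[paste0("target_", ti)]] <-
      Reduce(`&`, lapply(repc, function(cn) sc[[cn]] > 0))
  }
  ms <- new("MethylationScores", scores = sc, tissues = tissues,
            normFactor = NA_real_,
            scoreFormula = "sum of smoothed M over in-cluster probes overlapping the annotation")
  if (normalize) ms <- normalizeBetweenTissues(ms)
  ms
}

#' Between-tissue scale normalisation of methylation scores
#'
#' Accounts for differences in precipitation efficiency between the two
#' hybridised tissues: the non-reference tissue's scores (combined and
#' replicate-level) are divided by the median ratio
#' ms(other)/ms(reference) over annotations with a positive score in both
#' tissues. The factor is recorded in the object. Applying the
#' normalisation twice is a no-op (the second factor is 1).
#'
#' @param ms a [MethylationScores-class].
#' @return the normalised object with `normFactor` set.
#' @export
normalizeBetweenTissues <- function(ms) {
  sc <- ms@scores
  ref <- ms@tissues[1]; other <- ms@tissues[2]
  a <- sc[[paste0("ms_", ref)]]
  b <- sc[[paste0("ms_", other)]]
  co <- a > 0 & b > 0
  if (!any(co))
    stop("no annotation with positive scores in both tissues; ",
         "re-run with normalize = FALSE to skip normalisation explicitly")
  f <- stats::median(b[co] / a[co])
  for (cn in grep(paste0("^ms_", other), colnames(sc), value = TRUE))
    sc[[cn]] <- sc[[cn]] / f
  ms@scores <- sc
  ms@normFactor <- if (is.na(ms@normFactor)) f else ms@normFactor * f
  ms
}

#' Per-tissue target sets and their set algebra
#'
#' A gene is a target of a tissue when its methylation score is positive
#' in both replicates of that tissue. Returns the per-tissue sets plus
#' union, intersection and tissue-only sets with counts.
#'
#' @param ms a [MethylationScores-class].
#' @return a list with `perTissue` (named list of id vectors), `union`,
#'   `intersection`, `onlyFirst`, `onlySecond`, and a `counts` named
#'   integer vector.
#' @export
callTargets <- function(ms) {
  sc <- ms@scores
  t1 <- ms@tissues[1]; t2 <- ms@tissues[2]
  s1 <- sc$id[sc[[paste0("target_", t1)]]]
  s2 <- sc$id[sc[[paste0("target_", t2)]]]
  res <- list(perTissue = stats::setNames(list(s1, s2), c(t1, t2)),
              union = union(s1, s2),
              intersection = intersect(s1, s2),
              onlyFirst = setdiff(s1, s2),
              onlySecond = setdiff(s2, s1))
  res$counts <- c(stats::setNames(c(length(s1), length(s2)), c(t1, t2)),
                  union = length(res$union),
                  intersection = length(res$intersection))
  res
}
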