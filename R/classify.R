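#' Classify annotations into methylation classes
#'
#' Applies the numeric rules for tissue-specific and equal methylation to
#' the replicate-level score table. With tissues (A = reference, B =
#' other), per annotation:
#' \itemize{
#'   \item `non_target`: not a target of either tissue (a target has a
#'     positive score in both replicates of that tissue);
#'   \item `dM_plus` (A-specific): target in A, and (mean ratio
#'     ms(A)/ms(B) >= `ratioCut` or ms(B) = 0), and the two-sample
#'     Student t-test on replicate scores has p <= `alpha`, and
#'     |ms(A) - ms(B)| >= `diffCut`;
#'   \item `dL_plus`: the symmetric rule for B;
#'   \item `M_eq_L`: target in both tissues, 1/`ratioCut` < ratio <
#'     `ratioCut`, |diff| < `diffCut`, and the replicate relative SD
#'     (SD/mean per tissue) is at most `relSDCut`;
#'   \item `target_other`: targets failing both the differential and the
#'     equal criteria.
#' }
#' When both replicate groups have zero variance the t-test p is
#' undefined and the significance criterion is treated as met only if
#' |diff| >= `diffCut` (deterministic degenerate rule).
#'
#' @param ms a [MethylationScores-class].
#' @param alpha t-test significance level (default 0.05).
#' @param ratioCut fold-change cutoff on combined scores (default 2).
#' @param diffCut absolute score-difference cutoff (default 10).
#' @param relSDCut replicate relative-SD ceiling for the equal class
#'   (default 0.05, i.e. 5 percent).
#' @return data.frame: id, label, per-tissue means, ratio, diff, p,
#'   relative SDs. Labels partition the annotation set.
#' @export
classifyMethylation <- function(ms, alpha = 0.05, ratioCut = 2,
                                diffCut = 10, relSDCut = 0.05) {
  sc <- as.data.frame(ms@scores)
  tA <- ms@tissues[1]; tB <- ms@tissues[2]
  repA <- as.matrix(sc[grep(paste0("^ms_", tA, "_rep"), colnames(sc))])
  repB <- as.matrix(sc[grep(paste0("^ms_", tB, "_rep"), colnames(sc))])
  if (ncol(repA) < 2 || ncol(repB) < 2)
    stop("two replicates per tissue are required")
  mA <- sc[[paste0("ms_", tA)]]; mB <- sc[[paste0("ms_", tB)]]
  tgtA <- sc[[paste0("target_", tA)]]; tgtB <- sc[[paste0("target_", tB)]]

  n <- nrow(sc)
  lab <- character(n); p <- numeric(n); d <- numeric(n)
  rsdA <- numeric(n); rsdB <- numeric(n); ratio <- numeric(n)
  for (i in seq_len(n)) {
    tt <- .pooledT(repA[i, ], repB[i, ])
    p[i] <- tt$p; d[i] <- mA[i] - mB[i]
    ratio[i] <- if (mB[i] == 0) Inf * (mA[i] > 0) else mA[i] / mB[i]
    rsdA[i] <- .relSD(repA[i, ]); rsdB[i] <- .relSD(repB[i, ])
    sig <- if (is.na(p[i])) abs(d[i]) >= diffCut else p[i] <= alpha
    if (!tgtA[i] && !tgtB[i]) {
      lab[i] <- "non_target"
    } else if (tgtA[i] && (mB[i] == 0 || ratio[i] >= ratioCut) &&
               sig && abs(d[i]) >= diffCut) {
      lab[i] <- "dM_plus"
    } else if (tgtB[i] && (mA[i] == 0 || (mA[i] > 0 &&
               mB[i] / mA[i] >= ratioCut)) && sig &&
               abs(d[i]) >= diffCut) {
      lab[i] <- "dL_plus"
    } else if (tgtA[i] && tgtB[i] &&
               ratio[i] > 1 / ratioCut && ratio[i] < ratioCut &&
               abs(d[i]) < diffCut &&
               max(rsdA[i], rsdB[i], na.rm = TRUE) <= relSDCut) {
      lab[i] <- "M_eq_L"
    } else {
      lab[i] <- "target_other"
    }
  }
  data.frame(id = sc$id, label = lab,
             ms_A = mA, ms_B = mB, ratio = ratio, diff = d, p = p,
             relSD_A = rsdA, relSD_B = rsdB,
             stringsAsFactors = FALSE,
             row.names = sc$id) |>
    stats::setNames(c("id", "label", paste0("ms_", tA),
                      paste0("ms_", tB), "ratio", "diff", "p",
                      paste0("relSD_", tA), paste0("relSD_", tB)))
}

#' Bin genes by tissue expression difference
#'
#' Works on two replicate log2 intensity columns per tissue. A gene not
#' detected (mean log2 below `detectionThreshold`, or any non-finite
#' intensity) in either tissue is `not_expressed`. Expressed genes are
#' binned on delta = mean log2(A) - mean log2(B):
#' \itemize{
#'   \item `dXM_ge2`: delta >= `diffCutLog2` and t-test p <= `alpha`
#'     (tissue-specific, A-preferential);
#'   \item `dXL_le2`: delta <= -`diffCutLog2` and p <= `alpha`;
#'   \item `dXM_1_2` / `dXL_1_2`: intermediate bins with
#'     `equalCutLog2` <= |delta| < `diffCutLog2`;
#'   \item `X_M_eq_L`: |delta| < `equalCutLog2` and replicate relative SD
#'     <= `relSDCut` in both tissues;
#'   \item `other`: everything else (e.g. large delta without
#'     significance).
#' }
#'
#' @param expression data.frame with `gene_id` and
#'   `log2_<tissue>_rep<k>` columns (as written by the simulator).
#' @param tissues length-2 tissue labels, A first.
#' @param alpha,diffCutLog2,equalCutLog2,relSDCut rule parameters
#'   (defaults 0.05, 2, 1, 0.05).
#' @param detectionThreshold mean log2 intensity below which a tissue's
#'   signal counts as not detected (default 7).
#' @param expressed optional logical vector overriding the derived
#'   expressed call.
#' @return data.frame: gene_id, bin, dlog2, p. Bins partition the genes.
#' @export
classifyExpression <- function(expression, tissues = c("Me", "Le"),
                               alpha = 0.05, diffCutLog2 = 2,
                               equalCutLog2 = 1, relSDCut = 0.05,
                               detectionThreshold = 7,
                               expressed = NULL) {
  tA <- tissues[1]; tB <- tissues[2]
  repA <- as.matrix(expression[grep(paste0("^log2_", tA, "_rep"),
                                    colnames(expression))])
  repB <- as.matrix(expression[grep(paste0("^log2_", tB, "_rep"),
                                    colnames(expression))])
  stopifnot(ncol(repA) >= 2, ncol(repB) >= 2)
  n <- nrow(expression)
  mA <- rowMeans(repA); mB <- rowMeans(repB)
  finite <- apply(cbind(repA, repB), 1, function(x) all(is.finite(x)))
  if (is.null(expressed))
    expressed <- finite & (mA >= detectionThreshold |
                             mB >= detectionThreshold)
  bin <- character(n); dl <- numeric(n); p <- numeric(n)
  for (i in seq_len(n)) {
    if (!expressed[i] || !finite[i]) {
      bin[i] <- "not_expressed"; dl[i] <- NA_real_; p[i] <- NA_real_
      next
    }
    tt <- .pooledT(repA[i, ], repB[i, ])
    dl[i] <- mA[i] - mB[i]; p[i] <- tt$p
    sig <- if (is.na(p[i])) abs(dl[i]) >= diffCutLog2 else p[i] <= alpha
    rsd <- max(.relSD(repA[i, ]), .relSD(repB[i, ]), na.rm = TRUE)
    if (dl[i] >= diffCutLog2 && sig) {
      bin[i] <- "dXM_ge2"
    } else if (dl[i] <= -diffCutLog2 && sig) {
      bin[i] <- "dXL_le2"
    } else if (dl[i] >= equalCutLog2 && dl[i] < diffCutLog2) {
      bin[i] <- "dXM_1_2"
    } else if (dl[i] <= -equalCutLog2 && dl[i] > -diffCutLog2) {
      bin[i] <- "dXL_1_2"
    } else if (abs(dl[i]) < equalCutLog2 && !is.na(rsd) &&
               rsd <= relSDCut) {
      bin[i] <- "X_M_eq_L"
    } else {
      bin[i] <- "other"
    }
  }
  data.frame(gene_id = expression$gene_id, bin = bin, dlog2 = dl, p = p,
             stringsAsFactors = FALSE)
}

#' Spearman rank-correlation matrix across replicate columns
#'
#' Used for replicate-concordance checks of both M-value tracks and
#' expression intensities. Constant columns have undefined coefficients,
#' reported as `NA`.
#'
#' @param mat numeric matrix, observations x samples (>= 3 rows).
#' @return the Spearman correlation matrix.
#' @export
replicateConcordance <- function(mat) {
  mat <- as.matrix(mat)
  stopifnot(nrow(mat) >= 3)
  const <- apply(mat, 2, function(x) stats::sd(x) == 0)
  r <- suppressWarnings(stats::cor(mat, method = "spearman"))
  r[const, ] <- NA_real_
  r[, const] <- NA_real_
  diag(r) <- ifelse(const, NA_real_, 1)
  r
}
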