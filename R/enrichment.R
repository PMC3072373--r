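#' Fold enrichment of a category within a gene set
#'
#' fold = (|set ∩ category| / |set|) / (|background ∩ category| /
#' |background|): the frequency of the category inside the set relative
#' to its genome-background frequency.
#'
#' @param geneSet character vector of ids (subset of `background`).
#' @param category character vector of ids defining the category.
#' @param background character vector of ids, the gene universe.
#' @return list: observed, setSize, backgroundFrequency, expected, fold.
#'   `fold` is `NA` (with the reason in `note`) when the set is empty or
#'   the category has background frequency 0.
#' @export
foldEnrichment <- function(geneSet, category, background) {
  if (!all(geneSet %in% background))
    stop("geneSet must be a subset of background")
  obs <- length(intersect(geneSet, category))
  bgFreq <- length(intersect(background, category)) / length(background)
  res <- list(observed = obs, setSize = length(geneSet),
              backgroundFrequency = bgFreq,
              expected = length(geneSet) * bgFreq, fold = NA_real_,
              note = NA_character_)
  if (length(geneSet) == 0) {
    res$note <- "empty gene set"
  } else if (bgFreq == 0) {
    res$note <- "category absent from background"
  } else {
    res$fold <- (obs / length(geneSet)) / bgFreq
  }
  res
}

#' Chi-square test of a family's target frequency against the genome
#'
#' One-degree-of-freedom goodness-of-fit chi-square comparing the
#' observed split of a gene family into subset members and non-members
#' against the split expected from the subset's genome-wide frequency.
#' No continuity correction by default (set `yates = TRUE` for a
#' sensitivity check).
#'
#' @param nFamilyInSubset family members in the subset (e.g. targets).
#' @param nInFamily family size.
#' @param genomeSubsetTotal subset members in the genome.
#' @param genomeTotal genes in the genome.
#' @param yates apply the Yates continuity correction (default `FALSE`).
#' @return list: statistic, p, expected counts.
#' @export
chi2FamilyTest <- function(nFamilyInSubset, nInFamily, genomeSubsetTotal,
                           genomeTotal, yates = FALSE) {
  stopifnot(nFamilyInSubset >= 0, nFamilyInSubset <= nInFamily,
            genomeSubsetTotal <= genomeTotal, nInFamily <= genomeTotal)
  p0 <- genomeSubsetTotal / genomeTotal
  expc <- c(nInFamily * p0, nInFamily * (1 - p0))
  if (any(expc == 0))
    stop("expected count of zero; use hypergeometricTermTest() instead")
  obs <- c(nFamilyInSubset, nInFamily - nFamilyInSubset)
  dev <- abs(obs - expc)
  if (yates) dev <- pmax(0, dev - 0.5)
  stat <- sum(dev^2 / expc)
  list(statistic = stat,
       p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       expected = expc)
}

#' Upper-tail hypergeometric term-enrichment test
#'
#' P\[X >= observed\] when drawing `setSize` genes without replacement
#' from a background of `backgroundSize` genes of which
#' `termInBackground` carry the term.
#'
#' @param termInSet observed term members in the set.
#' @param setSize size of the gene set drawn.
#' @param termInBackground term members in the background.
#' @param backgroundSize background size.
#' @return the upper-tail p-value.
#' @examples hypergeometricTermTest(5, 5, 5, 10)  # 1/252
#' @export
hypergeometricTermTest <- function(termInSet, setSize, termInBackground,
                                   backgroundSize) {
  if (termInSet > min(setSize, termInBackground) ||
      setSize > backgroundSize || termInBackground > backgroundSize ||
      termInSet < 0)
    stop("inconsistent hypergeometric counts")
  stats::phyper(termInSet - 1, termInBackground,
                backgroundSize - termInBackground, setSize,
                lower.tail = FALSE)
}

#' Per-family target summary (printed-table style)
#'
#' For each family: total members, members in the methylation target
#' union, the percentage at one decimal (round half up), and optional
#' per-class counts when a class labelling is supplied.
#'
#' @param familyTable named list, family -> gene ids (see
#'   [readFamilyTable()]).
#' @param targetUnion character vector of target ids (union over
#'   tissues).
#' @param classes optional named character vector of methylation labels
#'   (names = gene ids), e.g. from [classifyMethylation()].
#' @param digits decimals of the printed percentage (default 1).
#' @return data.frame: family, n_total, n_target, percent_target and, if
#'   classes are given, n_dM_plus, n_dL_plus, n_M_eq_L.
#' @export
familyTargetSummary <- function(familyTable, targetUnion, classes = NULL,
                                digits = 1) {
  if (any(lengths(familyTable) == 0))
    stop("empty family: ",
         paste(names(familyTable)[lengths(familyTable) == 0],
               collapse = ", "))
  res <- data.frame(
    family = names(familyTable),
    n_total = lengths(familyTable),
    n_target = vapply(familyTable, function(g)
      length(intersect(g, targetUnion)), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  res$percent_target <- roundHalfUp(100 * res$n_target / res$n_total,
                                    digits)
  if (!is.null(classes)) {
    for (cl in c("dM_plus", "dL_plus", "M_eq_L")) {
      res[[paste0("n_", cl)]] <- vapply(familyTable, function(g)
        sum(classes[intersect(g, names(classes))] == cl), integer(1))
    }
  }
  res
}

#' Small-RNA locus / target-gene methylation coupling
#'
#' Summarises, per small-RNA family and in total, how many of the
#' family's loci carry the methylation mark and how many of the genes
#' the family regulates do. Percentages are recomputed from counts at
#' print time, never stored.
#'
#' @param lociTable named list, family -> locus ids.
#' @param targetMap named list, family -> regulated gene ids (may lack
#'   families with no known targets).
#' @param targetUnion character vector: ids (loci and genes) in the
#'   methylation target union.
#' @param registry optional annotation `GRanges`; when given, locus ids
#'   missing from it are an error.
#' @param digits decimals for the printed percentages (default 0,
#'   matching per-family table style).
#' @return list with `rows` (per-family data.frame) and `totals`
#'   (single-row data.frame; percentages `NA` when a denominator is 0).
#' @export
smallRNACoupling <- function(lociTable, targetMap, targetUnion,
                             registry = NULL, digits = 0) {
  if (!is.null(registry)) {
    missing <- setdiff(unlist(lociTable, use.names = FALSE),
                       names(registry))
    if (length(missing))
      stop("locus id(s) not in annotation registry: ",
           paste(utils::head(missing, 5), collapse = ", "))
  }
  fams <- names(lociTable)
  rows <- data.frame(
    family = fams,
    loci_total = lengths(lociTable)[fams],
    loci_targeted = vapply(lociTable, function(g)
      length(intersect(g, targetUnion)), integer(1))[fams],
    genes_total = vapply(fams, function(f)
      length(targetMap[[f]]), integer(1)),
    genes_targeted = vapply(fams, function(f)
      length(intersect(targetMap[[f]], targetUnion)), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  pct <- function(k, n) ifelse(n > 0, roundHalfUp(100 * k / n, digits),
                               NA_real_)
  rows$loci_percent <- pct(rows$loci_targeted, rows$loci_total)
  rows$genes_percent <- pct(rows$genes_targeted, rows$genes_total)
  totals <- data.frame(
    loci_total = sum(rows$loci_total),
    loci_targeted = sum(rows$loci_targeted),
    genes_total = sum(rows$genes_total),
    genes_targeted = sum(rows$genes_targeted))
  totals$loci_percent <- pct(totals$loci_targeted, totals$loci_total)
  totals$genes_percent <- pct(totals$genes_targeted, totals$genes_total)
  list(rows = rows, totals = totals)
}

#' Cross-tabulate expression bins against methylation classes
#'
#' For every (expression bin, methylation class) pair over a common gene
#' universe, computes the fold enrichment of the class within the bin
#' relative to the class's genome frequency, with a chi-square
#' significance test, in both directions (class-within-bin and
#' bin-within-class).
#'
#' @param methLabels named character vector, gene id -> methylation
#'   class.
#' @param exprBins named character vector, gene id -> expression bin.
#' @return data.frame with columns direction, bin, class, observed,
#'   set_size, background_frequency, fold, p.
#' @export
crosstabExpressionMethylation <- function(methLabels, exprBins) {
  universe <- intersect(names(methLabels), names(exprBins))
  if (length(universe) == 0)
    stop("methylation and expression labelings share no genes")
  methLabels <- methLabels[universe]
  exprBins <- exprBins[universe]
  out <- list()
  addDir <- function(setLab, catLab, direction) {
    for (s in unique(setLab)) {
      set <- universe[setLab == s]
      for (cl in unique(catLab)) {
        cat_ids <- universe[catLab == cl]
        fe <- foldEnrichment(set, cat_ids, universe)
        pv <- if (fe$backgroundFrequency %in% c(0, 1) ||
                  length(set) == 0) NA_real_ else
          chi2FamilyTest(fe$observed, length(set), length(cat_ids),
                         length(universe))$p
        out[[length(out) + 1L]] <<- data.frame(
          direction = direction, set = s, category = cl,
          observed = fe$observed, set_size = fe$setSize,
          background_frequency = fe$backgroundFrequency,
          fold = fe$fold, p = pv, stringsAsFactors = FALSE)
      }
    }
  }
  addDir(exprBins, methLabels, "meth_within_expr")
  addDir(methLabels, exprBins, "expr_within_meth")
  do.call(rbind, out)
}
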