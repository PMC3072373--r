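# ChIP-qPCR / qRT-PCR normalisation arithmetic used for locus-level
# confirmation of array calls. "nd" (not detectable) measurements enter
# as NA and propagate as NA, never as zero.

#' Percent of input recovered in a ChIP
#'
#' 100 * IP / (input / inputFraction), where `inputFraction` is the
#' fraction of chromatin kept aside as the input sample.
#'
#' @param ip,input positive quantities (same units).
#' @param inputFraction fraction of chromatin in the input aliquot, in
#'   (0, 1].
#' @return percent of input; `NA` inputs propagate.
#' @examples percentInput(0.05, 1, 0.1)  # 0.5
#' @export
percentInput <- function(ip, input, inputFraction = 1) {
  if (any(inputFraction <= 0 | inputFraction > 1))
    stop("inputFraction must be in (0, 1]")
  ok <- !is.na(ip) & !is.na(input)
  if (any(ip[ok] <= 0) || any(input[ok] <= 0))
    stop("qPCR quantities must be positive")
  100 * ip / (input / inputFraction)
}

#' Enrichment relative to a reference locus
#'
#' Ratio of a locus's percent-input to the reference locus's
#' percent-input from the same sample; the between-tissue enrichment
#' factor is the ratio of these normalised ratios across tissues.
#'
#' @param piLocus,piReference percent-input values from one sample.
#' @return the ratio; `NA` (reported with a warning) when the reference
#'   is 0, `NA` propagated when either value is missing.
#' @export
relativeEnrichment <- function(piLocus, piReference) {
  r <- piLocus / piReference
  zero <- !is.na(piReference) & piReference == 0
  if (any(zero)) {
    warning("reference percent-input of 0; enrichment undefined")
    r[zero] <- NA_real_
  }
  r
}

#' Between-tissue enrichment factor
#'
#' @param ratioTissueA,ratioTissueB reference-normalised enrichments of
#'   the same locus in two tissues.
#' @return ratioTissueA / ratioTissueB.
#' @export
tissueEnrichmentFactor <- function(ratioTissueA, ratioTissueB) {
  relativeEnrichment(ratioTissueA, ratioTissueB)
}

#' Expression relative to a reference gene
#'
#' Quantity mode: ratio of quantities. Cq mode (via
#' [relativeExpressionCq()]): efficiency^(Cq_ref - Cq_gene), with the
#' amplification efficiency fixed at 2 unless supplied.
#'
#' @param quantityGene,quantityReference positive expression quantities.
#' @return the ratio; missing reference is an error.
#' @export
relativeExpression <- function(quantityGene, quantityReference) {
  if (length(quantityReference) == 0 || all(is.na(quantityReference)))
    stop("reference quantity missing")
  relativeEnrichment(quantityGene, quantityReference)
}

#' @rdname relativeExpression
#' @param cqGene,cqReference quantification-cycle values.
#' @param efficiency amplification efficiency per cycle (default 2).
#' @export
relativeExpressionCq <- function(cqGene, cqReference, efficiency = 2) {
  stopifnot(efficiency > 1)
  efficiency^(cqReference - cqGene)
}
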