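#' Read a genome annotation registry from GFF3
#'
#' Records must carry an `ID` attribute (unique) and a `category`
#' attribute (one of protein_coding, miRNA, tasiRNA,
#' transposable_element, other; unknown values are kept verbatim).
#' Coordinates follow the GFF3 1-based inclusive convention and are kept
#' that way on the returned `GRanges`, so an input record start=100
#' end=200 has width 101.
#'
#' @param path GFF3 file.
#' @return `GRanges` named by `ID`, with `ID` and `category` metadata
#'   columns. An empty file yields an empty registry with a warning.
#' @export
readAnnotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e)
                   stop("malformed GFF3 in ", path, ": ",
                        conditionMessage(e)))
  if (length(gr) == 0) {
    warning("empty annotation file: ", path)
    return(gr)
  }
  ids <- mcols(gr)$ID
  if (is.null(ids) || anyNA(ids))
    stop("every GFF3 record needs an ID attribute")
  if (anyDuplicated(ids))
    stop("duplicate annotation id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (is.null(mcols(gr)$category))
    stop("annotations need a 'category' attribute")
  names(gr) <- ids
  gr
}

#' Write an annotation registry as GFF3
#'
#' @param gr annotation `GRanges` with `ID` and `category` columns.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeAnnotations <- function(gr, path) {
  out <- gr
  if (is.null(mcols(out)$type)) mcols(out)$type <- "gene"
  mcols(out)$source <- "tilemark"
  rtracklayer::export(out, path, format = "gff3")
  invisible(path)
}

#' Read probe tracks for all samples into one ProbeTrack
#'
#' Each file is a TSV with columns chrom, start, end, M (1-based
#' inclusive coordinates). All files must describe the identical probe
#' set; any coordinate mismatch is an error naming the offending probe.
#' Unsorted input is sorted with a warning.
#'
#' @param files character vector of file paths, one per sample.
#' @param tissue,replicate sample labels, parallel to `files`.
#' @return a [ProbeTrack-class].
#' @export
readProbeTracks <- function(files, tissue, replicate) {
  stopifnot(length(files) == length(tissue),
            length(files) == length(replicate))
  ref <- NULL
  M <- NULL
  for (j in seq_along(files)) {
    d <- utils::read.delim(files[j], stringsAsFactors = FALSE)
    if (!all(c("chrom", "start", "end", "M") %in% colnames(d)))
      stop("probe file ", files[j],
           " must have columns chrom, start, end, M")
    if (!is.numeric(d$M) || anyNA(d$M)) {
      bad <- which(is.na(suppressWarnings(as.numeric(d$M))))[1]
      stop("non-numeric M value in ", files[j], " at data line ", bad)
    }
    ord <- order(d$chrom, d$start)
    if (is.unsorted(ord)) {
      warning("probe file ", files[j], " was unsorted; sorting")
      d <- d[ord, ]
    }
    key <- paste(d$chrom, d$start, d$end)
    if (is.null(ref)) {
      ref <- d
      refkey <- key
      M <- matrix(NA_real_, nrow = nrow(d), ncol = length(files))
    } else {
      if (nrow(d) != nrow(ref) || any(key != refkey)) {
        i <- if (nrow(d) != nrow(ref)) 1L else which(key != refkey)[1]
        stop("probe coordinates differ across files at probe ", i,
             " (", files[j], ": ", key[min(i, length(key))], ")")
      }
    }
    M[, j] <- d$M
  }
  ProbeTrack(GRanges(ref$chrom, IRanges(ref$start, ref$end)),
             M, tissue, replicate)
}

#' Write called clusters as BED
#'
#' BED uses 0-based half-open coordinates; the conversion from the
#' 1-based closed ranges is handled by rtracklayer. The score column
#' carries the cluster's mean smoothed M.
#'
#' @param clusters `GRanges` of clusters (as in a [DomainCalls-class]
#'   element).
#' @param path output BED file.
#' @return invisibly, `path`.
#' @export
writeClustersBed <- function(clusters, path) {
  out <- granges(clusters)
  if (length(out)) {
    mcols(out)$name <- paste0("cluster_", seq_along(out))
    sc <- mcols(clusters)$mean_smoothed_M
    mcols(out)$score <- if (is.null(sc)) 0 else sc
  }
  rtracklayer::export(out, path, format = "bed")
  invisible(path)
}

#' Read clusters back from BED
#'
#' @param path BED file written by [writeClustersBed()].
#' @return `GRanges` with a `mean_smoothed_M` column.
#' @export
readClustersBed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  if (length(gr)) mcols(gr)$mean_smoothed_M <- mcols(gr)$score
  gr
}

#' Read a gene-family membership table
#'
#' TSV with columns `family` and `gene_id`; membership is many-to-many (a
#' gene may belong to several families). If a registry is given, ids that
#' do not resolve are reported in the `"unresolved"` attribute (never
#' silently dropped).
#'
#' @param path TSV file.
#' @param registry optional annotation `GRanges` (from
#'   [readAnnotations()]) to resolve ids against.
#' @return named list: family -> character vector of gene ids.
#' @export
readFamilyTable <- function(path, registry = NULL) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("family", "gene_id") %in% colnames(d)))
    stop("family table needs columns 'family' and 'gene_id'")
  fam <- split(d$gene_id, d$family)
  if (!is.null(registry)) {
    unresolved <- setdiff(unique(d$gene_id), names(registry))
    if (length(unresolved))
      warning(length(unresolved), " family member id(s) not in registry")
    attr(fam, "unresolved") <- unresolved
  }
  fam
}

#' Read a miRNA-to-target map
#'
#' TSV with columns `family` and `target_id` mapping each small-RNA
#' family to the protein-coding genes it regulates.
#'
#' @param path TSV file.
#' @return named list: family -> character vector of target gene ids.
#' @export
readMirnaTargetMap <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("family", "target_id") %in% colnames(d)))
    stop("target map needs columns 'family' and 'target_id'")
  split(d$target_id, d$family)
}
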