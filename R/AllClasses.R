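#' @import methods
#' @importFrom GenomeInfoDb Seqinfo seqnames seqlengths seqinfo
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importClassesFrom GenomicRanges GRanges
NULL

VALUE_KINDS <- c("coverage_fraction", "normalized_density", "log_ratio",
                 "eigenvector")

#' BinnedTrack: a fixed-width per-bin scalar signal over a genome
#'
#' One scalar per bin per chromosome, with the genome held as a
#' [GenomeInfoDb::Seqinfo]. The number of bins on each chromosome is
#' `ceiling(length / binSize)`; the terminal bin may be shorter than
#' `binSize` and its value is always computed over its true width.
#' Missing data are `NA` and are propagated, never zero-filled.
#'
#' @slot genome A `Seqinfo` describing chromosome names and lengths.
#' @slot binSize Bin width in base pairs.
#' @slot values Named list, one numeric vector per chromosome.
#' @slot valueKind One of `"coverage_fraction"`, `"normalized_density"`,
#'   `"log_ratio"`, `"eigenvector"`.
#'
#' @exportClass BinnedTrack
setClass("BinnedTrack",
  representation(genome = "Seqinfo", binSize = "integer",
                 values = "list", valueKind = "character"))

setValidity("BinnedTrack", function(object) {
  msg <- character()
  if (length(object@binSize) != 1L || is.na(object@binSize) ||
      object@binSize <= 0L)
    msg <- c(msg, "binSize must be a single positive integer")
  if (!(object@valueKind %in% VALUE_KINDS))
    msg <- c(msg, sprintf("valueKind must be one of: %s",
                          paste(VALUE_KINDS, collapse = ", ")))
  sl <- seqlengths(object@genome)
  if (!identical(sort(names(object@values)), sort(names(sl))))
    msg <- c(msg, "values must have one entry per chromosome in genome")
  else {
    expected <- ceiling(sl / object@binSize)
    got <- vapply(object@values[names(sl)], length, integer(1))
    if (!all(got == expected))
      msg <- c(msg, "bins per chromosome must equal ceiling(length/binSize)")
    if (object@valueKind == "coverage_fraction") {
      v <- unlist(object@values, use.names = FALSE)
      v <- v[!is.na(v)]
      if (length(v) && (min(v) < -1e-9 || max(v) > 1 + 1e-9))
        msg <- c(msg, "coverage_fraction values must lie in [0, 1]")
    }
  }
  if (length(msg)) msg else TRUE
})

#' EigenTrack: a compartment eigenvector with orientation metadata
#'
#' Extends [BinnedTrack-class] (valueKind `"eigenvector"`) with the sign
#' anchor used to orient the vector and the leading eigenvalue's share of
#' total variance. Positive values denote the A-like (B1/Alu-rich) state.
#'
#' @slot orientation `"anchored"` if the global sign was fixed against the
#'   anchor track, `"ambiguous"` if the anchor correlation was zero.
#' @slot varExplained Leading eigenvalue over the sum of positive
#'   eigenvalues, per chromosome.
#'
#' @exportClass EigenTrack
setClass("EigenTrack", contains = "BinnedTrack",
  representation(orientation = "character", varExplained = "numeric"))

#' CompartmentSet: labeled, non-overlapping genomic compartments
#'
#' Wraps a `GRanges` whose mcols carry a `label` (from a declared
#' two-letter alphabet such as B1-rich/L1-rich or A/B) and an optional
#' numeric `score` (mean log-ratio or eigenvalue).
#'
#' @slot regions `GRanges` with mcols `label` and `score`.
#' @slot alphabet Character vector of permitted labels.
#'
#' @exportClass CompartmentSet
setClass("CompartmentSet",
  representation(regions = "GRanges", alphabet = "character"))

setValidity("CompartmentSet", function(object) {
  msg <- character()
  gr <- object@regions
  if (!all(c("label") %in% names(mcols(gr))))
    msg <- c(msg, "regions must carry a 'label' metadata column")
  else if (!all(mcols(gr)$label %in% object@alphabet))
    msg <- c(msg, "all labels must belong to the declared alphabet")
  if (length(gr) && any(GenomicRanges::width(gr) < 1L))
    msg <- c(msg, "all regions must have start < end")
  if (length(gr) > 1L) {
    cov <- GenomicRanges::coverage(gr)
    if (any(vapply(cov, function(x) any(S4Vectors::runValue(x) > 1L),
                   logical(1))))
      msg <- c(msg, "regions within a set must not overlap")
  }
  if (length(msg)) msg else TRUE
})

#' ContactMatrix: a symmetric binned cis contact map for one chromosome
#'
#' @slot chrom Chromosome identifier.
#' @slot binSize Bin width in base pairs.
#' @slot counts Symmetric square numeric matrix of (possibly normalized)
#'   contact frequencies; `NA` marks masked pixels.
#' @slot normalization `"raw"`, `"balanced"` or `"oe"`.
#' @slot badBins Integer indices of bins excluded from statistics.
#'
#' @exportClass ContactMatrix
setClass("ContactMatrix",
  representation(chrom = "character", binSize = "integer",
                 counts = "matrix", normalization = "character",
                 badBins = "integer"))

setValidity("ContactMatrix", function(object) {
  msg <- character()
  m <- object@counts
  if (nrow(m) != ncol(m))
    msg <- c(msg, "counts must be square")
  else {
    d <- abs(m - t(m))
    if (any(d > 1e-6 * (abs(m) + 1), na.rm = TRUE))
      msg <- c(msg, "counts must be symmetric within numeric tolerance")
  }
  if (any(m < 0, na.rm = TRUE))
    msg <- c(msg, "counts must be non-negative")
  if (!(object@normalization %in% c("raw", "balanced", "oe")))
    msg <- c(msg, "normalization must be 'raw', 'balanced' or 'oe'")
  if (length(object@badBins) &&
      (min(object@badBins) < 1L || max(object@badBins) > nrow(m)))
    msg <- c(msg, "badBins out of range")
  if (length(msg)) msg else TRUE
})

#' SaddleResult: quantile-by-quantile mean O/E and compartment strength
#'
#' Bins are ranked by eigenvector value (ascending: B-like first) and cut
#' into equal-occupancy quantile groups; each cell holds the mean O/E over
#' cis bin pairs in that pair of groups. Strength is
#' (AA + BB) / (AB + BA) over the extreme-corner cells.
#'
#' @exportClass SaddleResult
setClass("SaddleResult",
  representation(saddle = "matrix", nQuantiles = "integer",
                 cornerFraction = "numeric", strength = "numeric"))

#' SegregationResult: homotypic/heterotypic contact ratio per chromosome
#'
#' @slot perChrom data.frame with columns chrom, homotypic, heterotypic,
#'   index.
#' @slot summary Mean index over autosomes (excluded chromosomes dropped).
#' @slot excluded Chromosomes left out of the summary.
#'
#' @exportClass SegregationResult
setClass("SegregationResult",
  representation(perChrom = "data.frame", summary = "numeric",
                 excluded = "character"))

#' OverlapReport: agreement of de novo compartments with Hi-C labels
#'
#' @slot assignments Per-compartment table (chrom, start, end, predicted
#'   label, majority Hi-C label, overlap fraction, consistent flag).
#' @slot consistentFraction Named numeric: per predicted label, the
#'   fraction of compartments whose majority Hi-C label agrees.
#'
#' @exportClass OverlapReport
setClass("OverlapReport",
  representation(assignments = "data.frame",
                 consistentFraction = "numeric"))

#' NucleusImage: two aligned intensity channels plus a nuclear mask
#'
#' @slot l1 Non-negative intensity array (2-D or 3-D), L1 channel.
#' @slot b1 Same-shape array, B1 channel.
#' @slot dna Optional DNA (DAPI) channel or `NULL`.
#' @slot mask Logical array of in-nucleus pixels or `NULL`.
#' @slot pixelSize Physical pixel size (length units), `NA` if unknown.
#'
#' @exportClass NucleusImage
setClass("NucleusImage",
  representation(l1 = "array", b1 = "array", dna = "ANY", mask = "ANY",
                 pixelSize = "numeric"))

setValidity("NucleusImage", function(object) {
  msg <- character()
  if (!identical(dim(object@l1), dim(object@b1)))
    msg <- c(msg, "l1 and b1 channels must share shape")
  if (!is.null(object@dna) && !identical(dim(object@dna), dim(object@l1)))
    msg <- c(msg, "dna channel must share shape with l1/b1")
  if (!is.null(object@mask)) {
    if (!identical(dim(object@mask), dim(object@l1)))
      msg <- c(msg, "mask must share shape with channels")
    else if (!any(object@mask))
      msg <- c(msg, "mask, if present, must be non-empty")
  }
  if (any(object@l1 < 0) || any(object@b1 < 0))
    msg <- c(msg, "intensities must be non-negative")
  if (length(msg)) msg else TRUE
})

#' FishIndexResult: the image-based segregation index for one nucleus
#'
#' The index is the negative Pearson correlation of the L1 and B1 signals
#' over in-nucleus pixels; +1 means perfectly segregated, -1 perfectly
#' colocalized.
#'
#' @exportClass FishIndexResult
setClass("FishIndexResult",
  representation(index = "numeric", nPixels = "integer",
                 maskProvenance = "character"))
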