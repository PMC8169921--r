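#' @include AllClasses.R
NULL

#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))
#' @export
setGeneric("valueKind", function(x) standardGeneric("valueKind"))
#' @export
setGeneric("trackValues", function(x, chrom = NULL)
  standardGeneric("trackValues"))
#' @export
setGeneric("regions", function(x) standardGeneric("regions"))
#' @export
setGeneric("compartmentLabels", function(x)
  standardGeneric("compartmentLabels"))
#' @export
setGeneric("segIndex", function(x) standardGeneric("segIndex"))
#' @export
setGeneric("strength", function(x) standardGeneric("strength"))
#' @export
setGeneric("badBins", function(x) standardGeneric("badBins"))

#' Accessors for repeatcomp classes
#'
#' `binSize()`, `valueKind()` and `trackValues()` read [BinnedTrack-class]
#' slots; `regions()` and `compartmentLabels()` read [CompartmentSet-class];
#' `counts()` and `badBins()` read [ContactMatrix-class]; `strength()` reads
#' [SaddleResult-class]; `segIndex()` reads [SegregationResult-class] (the
#' autosome summary) or [FishIndexResult-class] (the per-nucleus index).
#'
#' @param x An object of the documented class.
#' @param chrom Optional chromosome name; if given, `trackValues()` returns
#'   that chromosome's numeric vector instead of the full list.
#' @param object For `counts`, a `ContactMatrix`.
#' @param ... Ignored.
#' @return The slot value.
#' @name accessors
#' @aliases binSize valueKind trackValues regions compartmentLabels
#'   segIndex strength badBins
NULL

#' @rdname accessors
#' @export
setMethod("binSize", "BinnedTrack", function(x) x@binSize)
#' @rdname accessors
#' @export
setMethod("binSize", "ContactMatrix", function(x) x@binSize)
#' @rdname accessors
#' @export
setMethod("valueKind", "BinnedTrack", function(x) x@valueKind)
#' @rdname accessors
#' @export
setMethod("trackValues", "BinnedTrack", function(x, chrom = NULL) {
  if (is.null(chrom)) x@values else x@values[[chrom]]
})
#' @rdname accessors
#' @export
setMethod("seqinfo", "BinnedTrack", function(x) x@genome)
#' @rdname accessors
#' @export
setMethod("regions", "CompartmentSet", function(x) x@regions)
#' @rdname accessors
#' @export
setMethod("compartmentLabels", "CompartmentSet",
          function(x) mcols(x@regions)$label)
#' @rdname accessors
#' @importFrom BiocGenerics counts
#' @export
setMethod("counts", "ContactMatrix", function(object, ...) object@counts)
#' @rdname accessors
#' @export
setMethod("badBins", "ContactMatrix", function(x) x@badBins)
#' @rdname accessors
#' @export
setMethod("strength", "SaddleResult", function(x) x@strength)
#' @rdname accessors
#' @export
setMethod("segIndex", "SegregationResult", function(x) x@summary)
#' @rdname accessors
#' @export
setMethod("segIndex", "FishIndexResult", function(x) x@index)

setMethod("show", "BinnedTrack", function(object) {
  nb <- sum(vapply(object@values, length, integer(1)))
  nm <- sum(vapply(object@values, function(v) sum(is.na(v)), integer(1)))
  cat(sprintf("%s of kind '%s': %d chromosome(s), %d bp bins, %d bins (%d missing)\n",
              class(object), object@valueKind,
              length(seqnames(object@genome)), object@binSize, nb, nm))
})

setMethod("show", "EigenTrack", function(object) {
  callNextMethod()
  cat(sprintf("  orientation: %s; variance explained: %s\n",
              object@orientation,
              paste(sprintf("%.2f", object@varExplained), collapse = ", ")))
})

setMethod("show", "CompartmentSet", function(object) {
  tab <- table(factor(mcols(object@regions)$label, levels = object@alphabet))
  cat(sprintf("CompartmentSet: %d regions (%s)\n", length(object@regions),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
})

setMethod("show", "ContactMatrix", function(object) {
  cat(sprintf("ContactMatrix %s: %d x %d bins of %d bp, %s, %d bad bins\n",
              object@chrom, nrow(object@counts), ncol(object@counts),
              object@binSize, object@normalization, length(object@badBins)))
})

setMethod("show", "SaddleResult", function(object) {
  cat(sprintf("SaddleResult: %d quantiles, corner fraction %.2f, strength %.3f\n",
              object@nQuantiles, object@cornerFraction, object@strength))
})

setMethod("show", "SegregationResult", function(object) {
  cat(sprintf("SegregationResult: %d chromosome(s); autosome mean index %.3f",
              nrow(object@perChrom), object@summary))
  if (length(object@excluded))
    cat(sprintf(" (excluding %s)", paste(object@excluded, collapse = ", ")))
  cat("\n")
})

setMethod("show", "FishIndexResult", function(object) {
  cat(sprintf("FishIndexResult: index %.3f over %d pixels (mask: %s)\n",
              object@index, object@nPixels, object@maskProvenance))
})

setMethod("show", "OverlapReport", function(object) {
  cf <- object@consistentFraction
  cat(sprintf("OverlapReport: %d compartments; consistent %s\n",
              nrow(object@assignments),
              paste(sprintf("%s: %.1f%%", names(cf), 100 * cf),
                    collapse = ", ")))
})
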