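#' @include hic.R
#' @importFrom EBImage otsu fillHull bwlabel Image readImage makeBrush
#'   opening
NULL

#' Construct a NucleusImage
#'
#' @param l1,b1 Same-shape non-negative intensity arrays (2-D images or
#'   3-D stacks) for the L1 and B1 channels.
#' @param dna Optional DNA (DAPI) channel used for segmentation.
#' @param mask Optional logical in-nucleus mask; when absent one is
#'   derived with [nuclearMask()].
#' @param pixelSize Physical pixel size, `NA` if unknown.
#' @return A [NucleusImage-class].
#' @export
NucleusImage <- function(l1, b1, dna = NULL, mask = NULL,
                         pixelSize = NA_real_) {
  asArr <- function(x) { x <- as.array(x); storage.mode(x) <- "double"; x }
  new("NucleusImage", l1 = asArr(l1), b1 = asArr(b1),
      dna = if (is.null(dna)) NULL else asArr(dna),
      mask = if (is.null(mask)) NULL else array(as.logical(mask), dim(l1)),
      pixelSize = pixelSize)
}

# Otsu + hole filling + largest connected component, one 2-D plane
maskPlane <- function(x) {
  img <- Image(x)
  th <- otsu(img, range = range(x), levels = 256L)
  fg <- fillHull(img > th)
  labs <- bwlabel(fg)
  tab <- table(labs[labs > 0])
  if (!length(tab)) return(array(FALSE, dim(x)))
  keep <- as.integer(names(tab)[which.max(tab)])
  array(as.array(labs) == keep, dim(x))
}

#' Segment the nucleus from a DNA channel
#'
#' Global Otsu threshold (foreground = brighter side), holes filled,
#' largest connected component kept. 3-D stacks are segmented per plane.
#'
#' @param dna Non-constant 2-D or 3-D intensity array.
#' @return Logical array of the same shape.
#' @export
nuclearMask <- function(dna) {
  x <- as.array(dna)
  if (diff(range(x)) == 0) stop("constant image cannot be segmented")
  if (length(dim(x)) == 2L) return(maskPlane(x))
  out <- array(FALSE, dim(x))
  for (z in seq_len(dim(x)[3L])) out[, , z] <- maskPlane(x[, , z])
  out
}

#' Image-based (FISH) segregation index
#'
#' The negative Pearson correlation of the L1 and B1 intensities over
#' in-nucleus pixels: +1 means perfectly segregated signals, -1 perfect
#' colocalization. Raw intensities are used by default; an optional
#' morphological rolling-ball background subtraction is available. 3-D
#' stacks pool all masked voxels into a single coefficient.
#'
#' @param img A [NucleusImage-class]. When it has no mask, one is derived
#'   from the DNA channel (or, failing that, the summed L1+B1 signal).
#' @param backgroundRadius Optional radius (pixels) of a disc structuring
#'   element; when given, a morphological opening of each channel is
#'   subtracted before correlating.
#' @return A [FishIndexResult-class].
#' @export
fishSegregationIndex <- function(img, backgroundRadius = NULL) {
  mask <- img@mask
  provenance <- "provided"
  if (is.null(mask)) {
    provenance <- "auto"
    src <- if (!is.null(img@dna)) img@dna else img@l1 + img@b1
    mask <- nuclearMask(src)
  }
  l1 <- img@l1; b1 <- img@b1
  if (!is.null(backgroundRadius)) {
    subtractBg <- function(x) {
      brush <- makeBrush(2L * as.integer(backgroundRadius) + 1L, "disc")
      bg <- as.array(opening(Image(x), brush))
      pmax(x - bg, 0)
    }
    if (length(dim(l1)) == 2L) {
      l1 <- subtractBg(l1); b1 <- subtractBg(b1)
    } else {
      for (z in seq_len(dim(l1)[3L])) {
        l1[, , z] <- subtractBg(l1[, , z])
        b1[, , z] <- subtractBg(b1[, , z])
      }
    }
  }
  vl <- l1[mask]; vb <- b1[mask]
  if (length(vl) < 10L)
    stop("fewer than 10 masked pixels")
  if (stats::sd(vl) == 0 || stats::sd(vb) == 0)
    stop("undefined result: zero variance in a channel within the mask")
  new("FishIndexResult", index = -cor(vl, vb),
      nPixels = length(vl), maskProvenance = provenance)
}

#' Read a two-channel nucleus image from TIFF files
#'
#' Single- or multi-page TIFFs (multi-page stacks become 3-D arrays).
#'
#' @param l1Path,b1Path Paths to the L1 and B1 channel TIFFs.
#' @param dnaPath,maskPath Optional DNA channel and mask TIFFs.
#' @param pixelSize Physical pixel size to record, `NA` if unknown.
#' @return A [NucleusImage-class].
#' @export
readNucleusImage <- function(l1Path, b1Path, dnaPath = NULL,
                             maskPath = NULL, pixelSize = NA_real_) {
  rd <- function(p) {
    a <- as.array(readImage(p))
    if (length(dim(a)) > 3L) stop("expected grayscale TIFF: ", p)
    a
  }
  NucleusImage(rd(l1Path), rd(b1Path),
               dna = if (is.null(dnaPath)) NULL else rd(dnaPath),
               mask = if (is.null(maskPath)) NULL else rd(maskPath) > 0,
               pixelSize = pixelSize)
}
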