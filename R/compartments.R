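#' @include genome-repeats.R
NULL

#' Construct a CompartmentSet
#'
#' @param regions `GRanges` with a `label` metadata column (and optionally
#'   `score`); regions must not overlap.
#' @param alphabet Permitted labels; defaults to the labels present.
#' @return A [CompartmentSet-class].
#' @export
CompartmentSet <- function(regions, alphabet = NULL) {
  if (is.null(mcols(regions)$score))
    mcols(regions)$score <- rep(NA_real_, length(regions))
  if (is.null(alphabet))
    alphabet <- sort(unique(as.character(mcols(regions)$label)))
  new("CompartmentSet", regions = sort(regions), alphabet = alphabet)
}

#' Background-normalized log2(B1/L1) density track
#'
#' Per bin, the densities of the two families are normalized to their
#' genome-wide background fractions (defaults: 19% of the genome is L1,
#' 3% is B1) and the base-2 log of their ratio is taken:
#' `r = log2(((dB1 + eps)/fB1) / ((dL1 + eps)/fL1))`. Positive values mean
#' B1 enrichment relative to background (A-like), negative L1 enrichment
#' (B-like). Bins missing in either input are missing in the output.
#'
#' @param b1,l1 [BinnedTrack-class]s of kind `coverage_fraction` on the
#'   same genome and binning (compartment calling uses 100-kb bins).
#' @param fB1,fL1 Genome-background fractions of B1 and L1.
#' @param epsilon Pseudocount in coverage units keeping empty bins finite;
#'   the default 1e-4 is smaller than a single 10-bp element per 100-kb
#'   bin and cannot flip the sign of a populated bin.
#' @return A [BinnedTrack-class] of kind `log_ratio`.
#' @export
logRatioTrack <- function(b1, l1, fB1 = 0.03, fL1 = 0.19, epsilon = 1e-4) {
  stopifnot(fB1 > 0, fB1 < 1, fL1 > 0, fL1 < 1, epsilon > 0)
  if (!identical(seqlengths(b1@genome), seqlengths(l1@genome)) ||
      b1@binSize != l1@binSize)
    stop("mismatched binning between the B1 and L1 tracks")
  vals <- mapply(function(db1, dl1) {
    log2(((db1 + epsilon) / fB1) / ((dl1 + epsilon) / fL1))
  }, b1@values, l1@values[names(b1@values)], SIMPLIFY = FALSE)
  BinnedTrack(b1@genome, b1@binSize, vals, "log_ratio")
}

#' Call repeat-defined compartments from a log-ratio track
#'
#' Maximal runs of same-sign bins become candidate regions (r > 0:
#' B1-rich; r < 0: L1-rich; r = 0 or missing bins break runs). Regions
#' not longer than `minSize` are discarded, leaving gaps — flanking
#' same-sign regions are not merged across them. Each kept region carries
#' its mean r as score.
#'
#' @param ratio A [BinnedTrack-class] of kind `log_ratio`.
#' @param minSize Minimum region length in bp (default 500 kb; only
#'   longer regions are kept).
#' @return A [CompartmentSet-class] with labels `B1-rich`/`L1-rich`.
#' @export
callRepeatCompartments <- function(ratio, minSize = 500000) {
  if (ratio@valueKind != "log_ratio")
    stop("input track must be of kind 'log_ratio'")
  bs <- ratio@binSize
  sl <- seqlengths(ratio@genome)
  out <- list()
  for (ch in names(ratio@values)) {
    v <- ratio@values[[ch]]
    sgn <- sign(v)
    sgn[is.na(sgn)] <- 0
    r <- rle(sgn)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values != 0
    if (!any(keep)) next
    bpStart <- (starts[keep] - 1L) * bs + 1L
    bpEnd <- pmin(ends[keep] * bs, sl[[ch]])
    lab <- ifelse(r$values[keep] > 0, "B1-rich", "L1-rich")
    score <- mapply(function(a, b) mean(v[a:b]), starts[keep], ends[keep])
    big <- (bpEnd - bpStart + 1L) > minSize
    if (!any(big)) next
    out[[ch]] <- GRanges(ch, IRanges(bpStart[big], bpEnd[big]),
                         label = lab[big], score = score[big],
                         seqinfo = ratio@genome)
  }
  if (!length(out)) {
    warning("no compartments called (all bins missing, zero or short runs)")
    gr <- GRanges(seqinfo = ratio@genome)
    mcols(gr)$label <- character(0)
    mcols(gr)$score <- numeric(0)
    return(CompartmentSet(gr, alphabet = c("B1-rich", "L1-rich")))
  }
  CompartmentSet(sort(unlist(GenomicRanges::GRangesList(out),
                             use.names = FALSE)),
                 alphabet = c("B1-rich", "L1-rich"))
}

# per-predicted-region overlap width with each label of another set
overlapByLabel <- function(predicted, hic) {
  labs <- unique(as.character(mcols(regions(hic))$label))
  predGR <- regions(predicted)
  res <- matrix(0, nrow = length(predGR), ncol = length(labs),
                dimnames = list(NULL, labs))
  hicGR <- regions(hic)
  hits <- findOverlaps(predGR, hicGR, ignore.strand = TRUE)
  if (length(hits)) {
    w <- width(pintersect(predGR[S4Vectors::queryHits(hits)],
                          hicGR[S4Vectors::subjectHits(hits)],
                          ignore.strand = TRUE))
    lab <- as.character(mcols(hicGR)$label[S4Vectors::subjectHits(hits)])
    for (k in seq_along(hits))
      res[S4Vectors::queryHits(hits)[k], lab[k]] <-
        res[S4Vectors::queryHits(hits)[k], lab[k]] + w[k]
  }
  res
}

#' Score de novo compartment calls against Hi-C A/B annotation
#'
#' Each predicted compartment is assigned the Hi-C label covering the
#' majority (> 50%) of its length; exact ties and majority-uncovered
#' compartments are reported as `"unassigned"`. The consistent fraction
#' per predicted label is the count whose majority Hi-C label matches the
#' mapping, over all compartments of that label.
#'
#' @param predicted [CompartmentSet-class] of de novo calls.
#' @param hic [CompartmentSet-class] of Hi-C annotated compartments.
#' @param mapping Named character vector sending predicted labels to Hi-C
#'   labels; the default encodes B1-rich = A, L1-rich = B.
#' @return An [OverlapReport-class].
#' @export
overlapScore <- function(predicted, hic,
                         mapping = c("B1-rich" = "A", "L1-rich" = "B")) {
  predGR <- regions(predicted)
  if (!length(predGR)) stop("empty predicted compartment set")
  ov <- overlapByLabel(predicted, hic)
  w <- width(predGR)
  majority <- character(length(predGR))
  frac <- numeric(length(predGR))
  for (i in seq_along(predGR)) {
    share <- ov[i, ] / w[i]
    j <- which(share > 0.5)
    if (length(j) == 1L) {
      majority[i] <- colnames(ov)[j]
      frac[i] <- share[j]
    } else {
      majority[i] <- "unassigned"
      frac[i] <- if (ncol(ov)) max(share) else 0
    }
  }
  predLab <- as.character(mcols(predGR)$label)
  consistent <- majority == unname(mapping[predLab])
  consistent[is.na(consistent)] <- FALSE
  assignments <- data.frame(
    chrom = as.character(seqnames(predGR)),
    start = start(predGR) - 1L, end = end(predGR),
    predicted = predLab, majority = majority,
    overlapFraction = frac, consistent = consistent,
    stringsAsFactors = FALSE)
  cf <- vapply(names(mapping), function(l) {
    n <- sum(predLab == l)
    if (n == 0L) NA_real_ else sum(consistent[predLab == l]) / n
  }, numeric(1))
  new("OverlapReport", assignments = assignments, consistentFraction = cf)
}

#' Partition predicted compartments by their Hi-C assignment
#'
#' Returns the four concordant/discordant classes (e.g. `B1.A`, `B1.B`,
#' `L1.A`, `L1.B`) as labeled intervals; `L1.A` holds L1-rich regions
#' falling in Hi-C A compartments, and so on. Unassigned compartments are
#' dropped; every assigned compartment appears in exactly one class.
#'
#' @inheritParams overlapScore
#' @return A [CompartmentSet-class] over the four class labels.
#' @export
discordantRegions <- function(predicted, hic,
                              mapping = c("B1-rich" = "A", "L1-rich" = "B")) {
  rep <- overlapScore(predicted, hic, mapping)
  a <- rep@assignments
  predGR <- regions(predicted)
  fam <- sub("-rich$", "", a$predicted)
  keep <- a$majority != "unassigned"
  cls <- paste(fam, a$majority, sep = ".")
  alphabet <- as.vector(outer(sub("-rich$", "", names(mapping)),
                              sort(unique(unname(mapping))), paste,
                              sep = "."))
  gr <- predGR[keep]
  mcols(gr) <- DataFrame(label = cls[keep],
                         score = mcols(predGR)$score[keep])
  CompartmentSet(gr, alphabet = sort(alphabet))
}
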