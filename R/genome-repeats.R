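#' @include AllGenerics.R
#' @importFrom GenomicRanges GRanges tileGenome reduce findOverlaps
#'   pintersect width start end strand coverage binnedAverage
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb seqlevels
#' @importFrom stats cor
NULL

#' Construct a BinnedTrack
#'
#' @param genome A [GenomeInfoDb::Seqinfo] (see [readChromSizes()]).
#' @param binSize Bin width in bp.
#' @param values Named list of per-chromosome numeric vectors, or a single
#'   numeric vector when the genome has one chromosome.
#' @param valueKind One of `"coverage_fraction"`, `"normalized_density"`,
#'   `"log_ratio"`, `"eigenvector"`.
#' @return A [BinnedTrack-class].
#' @export
BinnedTrack <- function(genome, binSize, values, valueKind) {
  if (is.numeric(values) && length(seqnames(genome)) == 1L)
    values <- stats::setNames(list(values), seqnames(genome))
  new("BinnedTrack", genome = genome, binSize = as.integer(binSize),
      values = values, valueKind = valueKind)
}

#' Read a two-column chrom.sizes table
#'
#' @param path Path to a whitespace-delimited file of chromosome name and
#'   length in bp.
#' @return A [GenomeInfoDb::Seqinfo].
#' @export
readChromSizes <- function(path) {
  df <- utils::read.table(path, header = FALSE, col.names = c("chrom", "len"),
                          colClasses = c("character", "numeric"))
  if (any(duplicated(df$chrom))) stop("duplicate chromosome names in ", path)
  if (any(df$len <= 0)) stop("chromosome lengths must be positive")
  Seqinfo(seqnames = df$chrom, seqlengths = as.integer(df$len))
}

# exact-label or prefix matching of subfamily labels
matchSubfamily <- function(labels, subfamily, prefix = FALSE) {
  if (is.null(subfamily)) return(rep(TRUE, length(labels)))
  if (prefix) {
    hit <- rep(FALSE, length(labels))
    for (p in subfamily) hit <- hit | startsWith(labels, p)
    hit
  } else labels %in% subfamily
}

#' Parse a RepeatMasker .out file or repeat BED into annotated ranges
#'
#' Reads either the RepeatMasker `.out` dialect (3 header lines,
#' whitespace-delimited, 1-based inclusive query coordinates) or a 4-6
#' column BED (0-based half-open) with the subfamily label in column 4.
#' Coordinates are converted to the 1-based closed convention of
#' `GRanges`; records on chromosomes absent from `genome` are skipped with
#' a warning carrying the skip count, and surviving records are clipped to
#' chromosome bounds.
#'
#' @param path File path.
#' @param genome `Seqinfo` restricting and bounding the records.
#' @param subfamilies Optional character vector of subfamily labels to
#'   keep; `NULL` keeps all.
#' @param prefix If `TRUE`, `subfamilies` are matched as label prefixes
#'   (e.g. `"L1"` aggregates all L1Md_* subfamilies, the whole-subclass
#'   aggregation used throughout the density analyses).
#' @param format `"auto"` (default), `"out"` or `"bed"`.
#' @return A `GRanges` with a `subfamily` metadata column.
#' @export
readRepeatMasker <- function(path, genome, subfamilies = NULL,
                             prefix = FALSE, format = c("auto", "out", "bed")) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (format == "auto") {
    head1 <- if (length(lines)) trimws(lines[[1L]]) else ""
    format <- if (grepl("^SW\\b|perc|^\\s*score", head1, ignore.case = TRUE))
      "out" else "bed"
  }
  if (format == "out") {
    body <- lines[-seq_len(min(3L, length(lines)))]
    lineno <- seq_along(lines)[-seq_len(min(3L, length(lines)))]
    keep <- nzchar(trimws(body))
    body <- body[keep]; lineno <- lineno[keep]
    fields <- strsplit(trimws(body), "\\s+")
    nf <- lengths(fields)
    bad <- which(nf < 11L)
    if (length(bad))
      stop("malformed RepeatMasker line ", lineno[bad[1L]], " in ", path)
    chrom <- vapply(fields, `[[`, character(1), 5L)
    begin <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 6L)))
    endc  <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 7L)))
    bad <- which(is.na(begin) | is.na(endc) | begin < 1 | endc < begin)
    if (length(bad))
      stop("malformed RepeatMasker line ", lineno[bad[1L]], " in ", path)
    strd <- vapply(fields, `[[`, character(1), 9L)
    strd <- ifelse(strd == "C", "-", ifelse(strd == "+", "+", "*"))
    label <- vapply(fields, `[[`, character(1), 10L)
    start <- begin            # 1-based inclusive already matches GRanges
    end <- endc
  } else {
    keep <- nzchar(trimws(lines)) & !grepl("^(track|browser|#)", lines)
    body <- lines[keep]; lineno <- which(keep)
    fields <- strsplit(trimws(body), "\\s+")
    nf <- lengths(fields)
    bad <- which(nf < 4L)
    if (length(bad))
      stop("malformed BED line ", lineno[bad[1L]], " in ", path,
           " (need at least 4 columns: chrom start end subfamily)")
    chrom <- vapply(fields, `[[`, character(1), 1L)
    s0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
    e0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
    bad <- which(is.na(s0) | is.na(e0) | s0 < 0 | e0 <= s0)
    if (length(bad))
      stop("malformed BED line ", lineno[bad[1L]], " in ", path)
    label <- vapply(fields, `[[`, character(1), 4L)
    strd <- ifelse(nf >= 6L,
                   vapply(fields, function(f) if (length(f) >= 6L) f[[6L]] else "*",
                          character(1)), "*")
    strd[!strd %in% c("+", "-")] <- "*"
    start <- s0 + 1            # 0-based half-open -> 1-based closed
    end <- e0
  }
  known <- chrom %in% seqnames(genome)
  nskip <- sum(!known)
  if (nskip > 0L)
    warning(nskip, " record(s) on chromosomes absent from the genome ",
            "table were skipped")
  chrom <- chrom[known]; start <- start[known]; end <- end[known]
  strd <- strd[known]; label <- label[known]
  if (any(!nzchar(label))) stop("empty subfamily label in ", path)
  sel <- matchSubfamily(label, subfamilies, prefix)
  gr <- GRanges(chrom[sel], IRanges(pmax(start[sel], 1),
                                    pmin(end[sel],
                                         seqlengths(genome)[chrom[sel]])),
                strand = strd[sel], subfamily = label[sel],
                seqinfo = genome)
  sort(gr)
}

# reduce the records matching a subfamily query to a union of intervals
subfamilyUnion <- function(annotation, subfamily = NULL, prefix = FALSE) {
  sel <- matchSubfamily(mcols(annotation)$subfamily, subfamily, prefix)
  reduce(annotation[sel], ignore.strand = TRUE)
}

#' Bin the union coverage of a repeat subfamily
#'
#' Each bin's value is the fraction of its bases covered by the union of
#' matching elements (overlaps merged first, strand ignored). The terminal
#' bin of each chromosome may be shorter than `binSize`; its coverage is
#' divided by its true width.
#'
#' @inheritParams readRepeatMasker
#' @param annotation `GRanges` with a `subfamily` column
#'   (see [readRepeatMasker()]).
#' @param binSize Bin width in bp (the repeat analyses use 10 kb, the
#'   compartment caller 100 kb).
#' @param subfamily Labels (or prefixes) to aggregate; `NULL` for all.
#' @return A [BinnedTrack-class] of kind `coverage_fraction`.
#' @export
binCoverage <- function(annotation, genome, binSize, subfamily = NULL,
                        prefix = FALSE) {
  stopifnot(binSize > 0)
  merged <- subfamilyUnion(annotation, subfamily, prefix)
  bins <- tileGenome(genome, tilewidth = binSize,
                     cut.last.tile.in.chrom = TRUE)
  cov <- coverage(merged)
  # union coverage is 0/1 so the binned mean is the covered fraction
  bins <- binnedAverage(bins, cov[seqlevels(bins)], "frac")
  vals <- split(mcols(bins)$frac, as.character(seqnames(bins)))
  vals <- lapply(vals, as.numeric)
  BinnedTrack(genome, binSize, vals[seqnames(genome)], "coverage_fraction")
}

#' Correlate two binned tracks
#'
#' Bins missing in either track are excluded pairwise.
#'
#' @param a,b [BinnedTrack-class] objects on the same genome and binning.
#' @param method `"pearson"` or `"spearman"`.
#' @return The correlation coefficient.
#' @export
trackCorrelation <- function(a, b, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!identical(seqlengths(a@genome), seqlengths(b@genome)) ||
      a@binSize != b@binSize)
    stop("tracks must share genome and bin size")
  va <- unlist(a@values, use.names = FALSE)
  vb <- unlist(b@values, use.names = FALSE)
  ok <- !is.na(va) & !is.na(vb)
  if (sum(ok) < 3L)
    stop("undefined result: fewer than 3 complete bin pairs")
  r <- cor(va[ok], vb[ok], method = method)
  if (is.na(r))
    stop("undefined result: zero variance in a track")
  r
}

#' Per-interval repeat content
#'
#' Fraction of each query interval covered by the union of matching
#' elements, the statistic behind compartment- and TAD-level repeat
#' content comparisons.
#'
#' @inheritParams binCoverage
#' @param intervals `GRanges` of query intervals (compartments, TADs,
#'   shuffled controls).
#' @return Numeric vector in `[0, 1]`, one value per interval.
#' @export
intervalRepeatContent <- function(annotation, intervals, subfamily = NULL,
                                  prefix = FALSE) {
  if (any(width(intervals) == 0L)) stop("zero-length interval")
  merged <- subfamilyUnion(annotation, subfamily, prefix)
  hits <- findOverlaps(intervals, merged, ignore.strand = TRUE)
  ov <- width(pintersect(intervals[S4Vectors::queryHits(hits)],
                         merged[S4Vectors::subjectHits(hits)],
                         ignore.strand = TRUE))
  covered <- rep(0, length(intervals))
  if (length(hits)) {
    agg <- tapply(ov, S4Vectors::queryHits(hits), sum)
    covered[as.integer(names(agg))] <- as.numeric(agg)
  }
  covered / width(intervals)
}

# run expr with a locally-seeded RNG, restoring global state afterwards
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Shuffle intervals to random non-overlapping positions
#'
#' The negative control behind repeat-content comparisons: each interval
#' keeps its length and chromosome but is placed uniformly at random,
#' without overlap among the shuffled output.
#'
#' @param intervals `GRanges` to shuffle.
#' @param genome `Seqinfo` bounding placement.
#' @param seed Integer seed; a fixed seed reproduces the output exactly.
#' @param maxTries Placement attempts per interval before giving up.
#' @return A `GRanges` parallel to `intervals` (same lengths, same
#'   chromosomes, same metadata) at new positions.
#' @export
shuffleIntervals <- function(intervals, genome, seed, maxTries = 1000L) {
  withSeed(seed, {
    out <- intervals
    for (ch in unique(as.character(seqnames(intervals)))) {
      idx <- which(as.character(seqnames(intervals)) == ch)
      lens <- width(intervals)[idx]
      L <- seqlengths(genome)[[ch]]
      ord <- order(lens, decreasing = TRUE)       # big ones first
      placed <- IRanges()
      starts <- integer(length(idx))
      for (j in ord) {
        len <- lens[j]
        if (len > L) stop("interval longer than chromosome ", ch)
        ok <- FALSE
        for (try in seq_len(maxTries)) {
          s <- 1L + floor(stats::runif(1) * (L - len + 1))
          cand <- IRanges(s, s + len - 1L)
          if (!length(findOverlaps(cand, placed))) {
            placed <- c(placed, cand)
            starts[j] <- s
            ok <- TRUE
            break
          }
        }
        if (!ok)
          stop("could not place a ", len, "-bp interval on ", ch,
               " without overlap after ", maxTries, " tries")
      }
      GenomicRanges::ranges(out)[idx] <-
        IRanges(starts, starts + lens - 1L)
    }
    sort(out)
  })
}

#' TAD-level L1/B1 content anti-correlation
#'
#' Computes per-TAD L1 and B1 union coverage and their Pearson
#' correlation; strongly negative values reproduce, at TAD scale, the
#' mutual exclusion of the two repeat families.
#'
#' @param annotation Repeat `GRanges` (see [readRepeatMasker()]).
#' @param tads `GRanges` of at least 3 TAD intervals.
#' @param subfamilyA,subfamilyB Label (prefix) queries for the two
#'   families; defaults aggregate all L1 and all B1 subfamilies.
#' @return A list with `contentA`, `contentB` (per-TAD fractions) and `r`.
#' @export
tadContentCorrelation <- function(annotation, tads, subfamilyA = "L1",
                                  subfamilyB = "B1") {
  if (length(tads) < 3L) stop("need at least 3 TADs")
  a <- intervalRepeatContent(annotation, tads, subfamilyA, prefix = TRUE)
  b <- intervalRepeatContent(annotation, tads, subfamilyB, prefix = TRUE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("undefined result: zero variance in TAD contents")
  list(contentA = a, contentB = b, r = cor(a, b))
}
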