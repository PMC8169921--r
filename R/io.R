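#' @include compartments.R
#' @importFrom rtracklayer import export
NULL

# bins of a BinnedTrack as a GRanges with a 'score' column, NA bins kept
trackToGRanges <- function(track) {
  bins <- tileGenome(track@genome, tilewidth = track@binSize,
                     cut.last.tile.in.chrom = TRUE)
  mcols(bins)$score <-
    unlist(track@values[as.character(GenomeInfoDb::seqlevels(bins))],
           use.names = FALSE)
  bins
}

#' Write a BinnedTrack as bedGraph
#'
#' Four-column bedGraph (0-based half-open); missing bins are omitted and
#' come back as missing on read.
#'
#' @param track A [BinnedTrack-class].
#' @param path Output file.
#' @export
writeBedGraph <- function(track, path) {
  gr <- trackToGRanges(track)
  gr <- gr[!is.na(mcols(gr)$score)]
  export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph into a BinnedTrack
#'
#' @param path bedGraph file whose intervals are exact bins of the stated
#'   binning.
#' @param genome `Seqinfo` of the target genome.
#' @param binSize Bin width in bp.
#' @param valueKind Value kind to stamp on the track.
#' @return A [BinnedTrack-class]; bins absent from the file are `NA`.
#' @export
readBedGraph <- function(path, genome, binSize, valueKind = "log_ratio") {
  gr <- import(path, format = "bedGraph")
  vals <- lapply(stats::setNames(nm = seqnames(genome)), function(ch) {
    n <- ceiling(seqlengths(genome)[[ch]] / binSize)
    v <- rep(NA_real_, n)
    sel <- as.character(seqnames(gr)) == ch
    if (any(sel)) {
      idx <- (start(gr)[sel] - 1L) %/% binSize + 1L
      v[idx] <- mcols(gr)$score[sel]
    }
    v
  })
  BinnedTrack(genome, binSize, vals, valueKind)
}

#' Read and write compartment BED
#'
#' Five-column BED dialect: chrom, 0-based start, end, label, signed
#' score (mean log-ratio or eigenvalue; `.` when absent). Sorted by
#' (chromosome order of the genome, start) so reruns diff cleanly.
#'
#' @param x A [CompartmentSet-class].
#' @param path File path.
#' @param genome `Seqinfo` used to bound and order records on read.
#' @param alphabet Optional permitted labels on read.
#' @return `readCompartmentBED` returns a [CompartmentSet-class].
#' @export
writeCompartmentBED <- function(x, path) {
  gr <- regions(x)
  sc <- mcols(gr)$score
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr),
                   label = as.character(mcols(gr)$label),
                   score = ifelse(is.na(sc), ".", format(sc, digits = 10)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeCompartmentBED
#' @export
readCompartmentBED <- function(path, genome, alphabet = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "label",
                                        "score")[1:5],
                          colClasses = c("character", "numeric", "numeric",
                                         "character", "character"),
                          fill = TRUE)
  score <- suppressWarnings(as.numeric(df$score))
  gr <- GRanges(df$chrom, IRanges(df$start + 1L, df$end),
                label = df$label, score = score, seqinfo = genome)
  CompartmentSet(gr, alphabet = alphabet)
}

#' Write/read a generic interval set as BED
#'
#' @param gr A `GRanges`; a `label` (or `name`) column becomes BED
#'   column 4.
#' @param path File path.
#' @param genome `Seqinfo` for the read side.
#' @export
writeBED <- function(gr, path) {
  lab <- mcols(gr)$label
  if (is.null(lab)) lab <- mcols(gr)$name
  if (is.null(lab)) lab <- rep(".", length(gr))
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr), name = lab)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeBED
#' @export
readBED <- function(path, genome) {
  gr <- import(path, format = "bed")
  GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(genome)
  GenomeInfoDb::seqinfo(gr) <- genome
  if (!is.null(mcols(gr)$name)) {
    mcols(gr)$label <- mcols(gr)$name
    mcols(gr)$name <- NULL
  }
  sort(gr)
}

#' Construct a ContactMatrix
#'
#' @param chrom Chromosome name.
#' @param binSize Bin width in bp.
#' @param counts Symmetric square matrix.
#' @param normalization `"raw"`, `"balanced"` or `"oe"`.
#' @param badBins Bin indices excluded from statistics; by default, bins
#'   whose row is entirely zero or missing.
#' @return A [ContactMatrix-class].
#' @export
ContactMatrix <- function(chrom, binSize, counts, normalization = "raw",
                          badBins = NULL) {
  if (is.null(badBins)) {
    rs <- rowSums(counts, na.rm = TRUE)
    allna <- apply(counts, 1L, function(x) all(is.na(x)))
    badBins <- which(rs == 0 | allna)
  }
  new("ContactMatrix", chrom = chrom, binSize = as.integer(binSize),
      counts = counts, normalization = normalization,
      badBins = as.integer(badBins))
}

#' Read and write dense per-chromosome contact matrices
#'
#' Whitespace-delimited square matrix of contact counts, one row per bin,
#' no headers.
#'
#' @param m A [ContactMatrix-class].
#' @param path File path.
#' @param chrom,binSize Chromosome name and bin width for the read side.
#' @param normalization Normalization state to stamp on the read matrix.
#' @export
writeDenseMatrix <- function(m, path) {
  utils::write.table(counts(m), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeDenseMatrix
#' @export
readDenseMatrix <- function(path, chrom, binSize, normalization = "raw") {
  x <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(x) <- NULL
  ContactMatrix(chrom, binSize, x, normalization)
}

#' Read and write contact matrices as a COO pixel table
#'
#' Plain-text triplet dialect of a single-resolution binned contact
#' container (as produced by dumping a cooler): a header line then rows
#' of `bin1_id  bin2_id  count` with 0-based bin ids, upper triangle
#' only.
#'
#' @param m A [ContactMatrix-class].
#' @param path File path.
#' @param chrom Chromosome name.
#' @param chromLength Chromosome length in bp (fixes the matrix size).
#' @param binSize Bin width in bp.
#' @param normalization Normalization state to stamp on the read matrix.
#' @export
writeContactPixels <- function(m, path) {
  x <- counts(m)
  ut <- which(upper.tri(x, diag = TRUE) & x != 0 & !is.na(x),
              arr.ind = TRUE)
  df <- data.frame(bin1_id = ut[, 1L] - 1L, bin2_id = ut[, 2L] - 1L,
                   count = x[ut])
  df <- df[order(df$bin1_id, df$bin2_id), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname writeContactPixels
#' @export
readContactPixels <- function(path, chrom, chromLength, binSize,
                              normalization = "raw") {
  df <- utils::read.table(path, header = TRUE)
  n <- ceiling(chromLength / binSize)
  if (any(df$bin1_id < 0 | df$bin2_id >= n))
    stop("pixel bin ids out of range for ", chrom)
  x <- matrix(0, n, n)
  x[cbind(df$bin1_id + 1L, df$bin2_id + 1L)] <- df$count
  x[cbind(df$bin2_id + 1L, df$bin1_id + 1L)] <- df$count
  ContactMatrix(chrom, binSize, x, normalization)
}

#' Write saddle and segregation results
#'
#' The saddle goes out as a tab-separated quantile-by-quantile matrix
#' plus a JSON summary (`strength`, `n_quantiles`, `corner_fraction`);
#' the segregation result as a per-chromosome table.
#'
#' @param x A [SaddleResult-class] or [SegregationResult-class].
#' @param prefix Output path prefix for the saddle writer.
#' @param path Output file for the segregation writer.
#' @export
writeSaddle <- function(x, prefix) {
  utils::write.table(x@saddle, paste0(prefix, ".saddle.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(strength = x@strength, n_quantiles = x@nQuantiles,
         corner_fraction = x@cornerFraction),
    paste0(prefix, ".saddle.json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname writeSaddle
#' @export
writeSegregation <- function(x, path) {
  utils::write.table(x@perChrom, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
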