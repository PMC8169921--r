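suppressPackageStartupMessages({
  library(GenomicRanges)
  library(GenomeInfoDb)
})

tinyGenome <- function(lens = c(chr1 = 100000L)) {
  Seqinfo(seqnames = names(lens), seqlengths = unname(lens))
}

repeatGR <- function(chrom, start, end, subfamily, genome,
                     strand = "*") {
  GRanges(chrom, IRanges(start, end), strand = strand,
          subfamily = subfamily, seqinfo = genome)
}

# one-chromosome log-ratio track from a plain numeric vector
ratioTrack <- function(v, binSize = 100000L, chromLen = NULL) {
  if (is.null(chromLen)) chromLen <- length(v) * binSize
  g <- tinyGenome(c(chr1 = as.integer(chromLen)))
  BinnedTrack(g, binSize, list(chr1 = v), "log_ratio")
}

coverageTrack <- function(v, binSize = 100000L) {
  g <- tinyGenome(c(chr1 = as.integer(length(v) * binSize)))
  BinnedTrack(g, binSize, list(chr1 = v), "coverage_fraction")
}

# alternating fixed-size two-label compartment annotation
alternatingCompartments <- function(chrom = "chr1", blockLen = 2e6,
                                    nBlocks = 20L,
                                    labels = c("A", "B"),
                                    genome = NULL) {
  starts <- (seq_len(nBlocks) - 1) * blockLen + 1
  if (is.null(genome)) {
    gr <- GRanges(chrom, IRanges(starts, starts + blockLen - 1),
                  label = rep(labels, length.out = nBlocks))
  } else {
    gr <- GRanges(chrom, IRanges(starts, starts + blockLen - 1),
                  label = rep(labels, length.out = nBlocks),
                  seqinfo = genome)
  }
  CompartmentSet(gr, alphabet = sort(labels))
}

# exact plaid O/E ContactMatrix from a label vector
plaidOE <- function(labels, homotypic = 2, heterotypic = 0.5,
                    binSize = 100000L) {
  same <- outer(labels, labels, "==")
  x <- matrix(heterotypic, length(labels), length(labels))
  x[same] <- homotypic
  ContactMatrix("chr1", binSize, x, "oe", badBins = integer(0))
}

writeTempLines <- function(lines) {
  f <- tempfile()
  writeLines(lines, f)
  f
}
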