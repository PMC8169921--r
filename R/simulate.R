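#' @include image.R
NULL

#' Specification of a synthetic repeat genome
#'
#' Chromosomes are tiled by alternating B1-rich / L1-rich blocks with
#' log-normally distributed lengths (median ~1.5 Mb, the megabase scale
#' of real compartments). Within each block, elements of both families
#' are placed uniformly at random without same-family overlap until the
#' block's target coverage is reached. Element lengths follow the
#' families' characteristic sizes: full-scale L1 at 6-7 kb, B1/Alu-scale
#' SINEs at 150-300 bp. Default block coverages (L1 0.30/0.05, B1
#' 0.08/0.01 in own/other blocks) bracket the genome-background fractions
#' (19% L1, 3% B1) so the signed density contrast is guaranteed.
#'
#' @param nChroms Number of chromosomes (default 5).
#' @param chromLength Chromosome length in bp (default 40 Mb).
#' @param blockLengthMedian Median block length in bp (default 1.5 Mb).
#' @param blockLengthSdLog Log-scale SD of block lengths (default 0.3).
#' @param l1CovL1Block,l1CovB1Block L1 coverage in L1- and B1-blocks.
#' @param b1CovB1Block,b1CovL1Block B1 coverage in B1- and L1-blocks.
#' @param l1LengthRange,b1LengthRange Element length ranges in bp.
#' @param seed Integer seed; generators are pure functions of the spec.
#' @return A `SyntheticGenomeSpec` object.
#' @export
SyntheticGenomeSpec <- function(nChroms = 5L, chromLength = 40e6,
                                blockLengthMedian = 1.5e6,
                                blockLengthSdLog = 0.3,
                                l1CovL1Block = 0.30, l1CovB1Block = 0.05,
                                b1CovB1Block = 0.08, b1CovL1Block = 0.01,
                                l1LengthRange = c(6000, 7000),
                                b1LengthRange = c(150, 300),
                                seed = 1L) {
  stopifnot(nChroms >= 1, chromLength > 0,
            l1CovL1Block >= 0, l1CovL1Block < 1,
            b1CovB1Block >= 0, b1CovB1Block < 1,
            l1CovL1Block > l1CovB1Block, b1CovB1Block > b1CovL1Block)
  structure(list(nChroms = as.integer(nChroms), chromLength = chromLength,
                 blockLengthMedian = blockLengthMedian,
                 blockLengthSdLog = blockLengthSdLog,
                 l1CovL1Block = l1CovL1Block, l1CovB1Block = l1CovB1Block,
                 b1CovB1Block = b1CovB1Block, b1CovL1Block = b1CovL1Block,
                 l1LengthRange = l1LengthRange, b1LengthRange = b1LengthRange,
                 seed = as.integer(seed)),
            class = "SyntheticGenomeSpec")
}

#' Specification of a synthetic plaid contact matrix
#'
#' Expected contacts follow a power-law distance decay modulated by label
#' affinity: `E[C_ij] = depth * (sep_bp)^(-alpha) * A(l_i, l_j)` with
#' `A = aHom` for same-label bins, `aHet` for cross-label pairs and 1 for
#' gap bins; counts are Poisson-sampled and symmetrized. `mitoticMode`
#' suppresses the affinity structure (A = 1) and boosts separations below
#' 1 Mb, emulating the diagonal-dominant mitotic contact pattern.
#'
#' @param binSize Bin width in bp (default 100 kb).
#' @param alpha Distance-decay exponent (default 1.0).
#' @param aHom,aHet Homotypic/heterotypic affinities (defaults 1.5,
#'   0.67, a planted homotypic/heterotypic ratio of ~2.25).
#' @param depth Sequencing-depth scale (default 1e7, giving a mean of
#'   ~10 counts per pixel at 1 Mb separation).
#' @param mitoticMode Logical; see above.
#' @param mitoticBoost Near-diagonal multiplier in mitotic mode.
#' @param seed Integer seed.
#' @return A `SyntheticHiCSpec` object.
#' @export
SyntheticHiCSpec <- function(binSize = 100000L, alpha = 1.0, aHom = 1.5,
                             aHet = 0.67, depth = 1e7,
                             mitoticMode = FALSE, mitoticBoost = 8,
                             seed = 1L) {
  stopifnot(aHom > 0, aHet > 0, aHom >= aHet, depth > 0, binSize > 0)
  structure(list(binSize = as.integer(binSize), alpha = alpha, aHom = aHom,
                 aHet = aHet, depth = depth, mitoticMode = mitoticMode,
                 mitoticBoost = mitoticBoost, seed = as.integer(seed)),
            class = "SyntheticHiCSpec")
}

#' Specification of a synthetic two-channel nucleus image
#'
#' `segregated` mode concentrates the L1 signal in a rim annulus plus an
#' inner nucleolar shell while B1 fills the interior (puncta on a base
#' level) away from the L1 field; `mixed` mode draws both channels from
#' one shared smooth random field, the pattern of a nucleus whose two
#' signals are spatially indistinguishable. Poisson-Gaussian noise is
#' added at the stated signal-to-noise ratio; the DNA channel is the
#' filled nuclear disk.
#'
#' @param size Image side in pixels (default 128).
#' @param radius Nucleus radius in pixels (default 48).
#' @param mode `"segregated"` or `"mixed"`.
#' @param snr Peak signal-to-noise ratio (default 10).
#' @param seed Integer seed.
#' @return A `SyntheticImageSpec` object.
#' @export
SyntheticImageSpec <- function(size = 128L, radius = 48L,
                               mode = c("segregated", "mixed"), snr = 10,
                               seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(radius < size / 2, snr > 0)
  structure(list(size = as.integer(size), radius = as.integer(radius),
                 mode = mode, snr = snr, seed = as.integer(seed)),
            class = "SyntheticImageSpec")
}

# place n non-overlapping intervals of given lengths uniformly in
# [lo, lo + span): order-statistics gap construction
placeNonOverlapping <- function(lengths, lo, span) {
  n <- length(lengths)
  if (!n) return(integer(0))
  slack <- span - sum(lengths)
  if (slack < 0) stop("packing failure: target coverage unattainable")
  gaps <- sort(stats::runif(n, 0, slack))
  starts <- lo + floor(gaps) + cumsum(c(0, lengths[-n]))
  as.integer(starts)
}

# element lengths drawn until the cumulative sum crosses the target
drawLengths <- function(target, range) {
  if (target <= 0) return(integer(0))
  lens <- integer(0)
  repeat {
    nGuess <- max(5L, ceiling((target - sum(lens)) / mean(range) * 1.3))
    lens <- c(lens, as.integer(round(stats::runif(nGuess, range[1L],
                                                  range[2L]))))
    cum <- cumsum(lens)
    if (any(cum >= target))
      return(lens[seq_len(which(cum >= target)[1L])])
  }
}

#' Simulate a repeat-annotated genome with planted compartments
#'
#' @param spec A [SyntheticGenomeSpec()].
#' @return A list: `annotation` (repeat `GRanges` with `subfamily`),
#'   `truth` (the planted [CompartmentSet-class], labels
#'   B1-rich/L1-rich), `genome` (`Seqinfo`).
#' @export
simulateRepeatGenome <- function(spec) {
  withSeed(spec$seed, {
    chroms <- paste0("chr", seq_len(spec$nChroms))
    genome <- Seqinfo(seqnames = chroms,
                      seqlengths = rep(as.integer(spec$chromLength),
                                       spec$nChroms))
    l1sub <- c("L1Md_T", "L1Md_A", "L1Md_F2")
    b1sub <- c("B1_Mus1", "B1_Mus2", "B1_Mm")
    annOut <- list(); truthOut <- list()
    for (ch in chroms) {
      L <- spec$chromLength
      nGuess <- ceiling(L / spec$blockLengthMedian * 2) + 5L
      blens <- stats::rlnorm(nGuess, log(spec$blockLengthMedian),
                             spec$blockLengthSdLog)
      blens <- as.integer(round(blens[cumsum(blens) < L]))
      blens <- c(blens, as.integer(L) - sum(blens)) # final block fills out
      blens <- blens[blens > 0L]
      bstart <- cumsum(c(0L, blens[-length(blens)])) + 1L
      bend <- cumsum(blens)
      first <- sample(c("B1-rich", "L1-rich"), 1L)
      other <- setdiff(c("B1-rich", "L1-rich"), first)
      lab <- rep(c(first, other), length.out = length(blens))
      truthOut[[ch]] <- GRanges(ch, IRanges(bstart, bend),
                                label = lab, seqinfo = genome)
      recs <- list()
      for (k in seq_along(blens)) {
        span <- blens[k]
        for (fam in c("L1", "B1")) {
          cov <- if (fam == "L1") {
            if (lab[k] == "L1-rich") spec$l1CovL1Block else spec$l1CovB1Block
          } else {
            if (lab[k] == "B1-rich") spec$b1CovB1Block else spec$b1CovL1Block
          }
          rng <- if (fam == "L1") spec$l1LengthRange else spec$b1LengthRange
          lens <- drawLengths(cov * span, rng)
          if (!length(lens)) next
          lens <- lens[sample.int(length(lens))]
          starts <- placeNonOverlapping(lens, bstart[k], span)
          subs <- sample(if (fam == "L1") l1sub else b1sub,
                         length(lens), replace = TRUE)
          recs[[paste(k, fam)]] <-
            GRanges(ch, IRanges(starts, width = lens),
                    strand = sample(c("+", "-"), length(lens),
                                    replace = TRUE),
                    subfamily = subs, seqinfo = genome)
        }
      }
      annOut[[ch]] <- sort(unlist(GenomicRanges::GRangesList(recs),
                                  use.names = FALSE))
    }
    truth <- sort(unlist(GenomicRanges::GRangesList(truthOut),
                         use.names = FALSE))
    mcols(truth)$score <- NA_real_
    list(annotation = sort(unlist(GenomicRanges::GRangesList(annOut),
                                  use.names = FALSE)),
         truth = CompartmentSet(truth, alphabet = c("B1-rich", "L1-rich")),
         genome = genome)
  })
}

#' Simulate a plaid (or mitotic-like) contact matrix
#'
#' @param truth A [CompartmentSet-class] labeling one chromosome (gaps
#'   allowed: uncovered bins get neutral affinity 1).
#' @param spec A [SyntheticHiCSpec()].
#' @param chrom Chromosome to simulate (default: the first in `truth`).
#' @param chromLength Chromosome length in bp; defaults to the end of the
#'   last labeled region.
#' @return A raw [ContactMatrix-class].
#' @export
simulateContactMatrix <- function(truth, spec, chrom = NULL,
                                  chromLength = NULL) {
  gr <- regions(truth)
  if (is.null(chrom)) chrom <- as.character(seqnames(gr))[1L]
  gr <- gr[as.character(seqnames(gr)) == chrom]
  if (!length(gr)) stop("truth has no regions on ", chrom)
  if (is.null(chromLength)) {
    chromLength <- seqlengths(seqinfo(gr))[[chrom]]
    if (is.na(chromLength)) chromLength <- max(end(gr))
  }
  bs <- spec$binSize
  n <- as.integer(ceiling(chromLength / bs))
  mid <- (seq_len(n) - 1) * bs + bs / 2
  pts <- GRanges(chrom, IRanges(round(mid), width = 1L))
  hits <- findOverlaps(pts, gr, ignore.strand = TRUE)
  lab <- rep(NA_character_, n)
  lab[S4Vectors::queryHits(hits)] <-
    as.character(mcols(gr)$label[S4Vectors::subjectHits(hits)])
  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  sepBp <- pmax(sep, 1L) * bs
  A <- matrix(1, n, n)
  if (!spec$mitoticMode) {
    same <- outer(lab, lab, "==")
    known <- outer(!is.na(lab), !is.na(lab), "&")
    A[known & same] <- spec$aHom
    A[known & !same] <- spec$aHet
  }
  E <- spec$depth * sepBp^(-spec$alpha) * A
  if (spec$mitoticMode) E[sep * bs < 1e6] <- E[sep * bs < 1e6] * spec$mitoticBoost
  withSeed(spec$seed, {
    ut <- upper.tri(E, diag = TRUE)
    x <- matrix(0, n, n)
    x[ut] <- stats::rpois(sum(ut), E[ut])
    x <- x + t(x) - diag(diag(x))
    ContactMatrix(chrom, bs, x, "raw")
  })
}

# a smooth random field on an r x r grid: random-phase cosine mixture
smoothField <- function(size, nWaves = 6L, scale = 0.12) {
  xy <- seq_len(size)
  f <- matrix(0, size, size)
  for (w in seq_len(nWaves)) {
    kx <- stats::runif(1, 0.5, 3) * 2 * pi / (size * scale * 8)
    ky <- stats::runif(1, 0.5, 3) * 2 * pi / (size * scale * 8)
    ph <- stats::runif(2, 0, 2 * pi)
    f <- f + outer(cos(kx * xy + ph[1L]), cos(ky * xy + ph[2L]))
  }
  f <- f - min(f)
  f / max(f)
}

#' Simulate a two-channel nucleus image
#'
#' @param spec A [SyntheticImageSpec()].
#' @return A [NucleusImage-class] (mask left unset so segmentation is
#'   exercised downstream; the DNA channel is the filled disk).
#' @export
simulateNucleusImages <- function(spec) {
  withSeed(spec$seed, {
    sz <- spec$size; R <- spec$radius
    ctr <- (sz + 1) / 2
    g <- expand.grid(x = seq_len(sz), y = seq_len(sz))
    r <- matrix(sqrt((g$x - ctr)^2 + (g$y - ctr)^2), sz, sz)
    disk <- r <= R
    if (spec$mode == "segregated") {
      rim <- exp(-(r - 0.88 * R)^2 / (2 * (0.06 * R)^2))
      shell <- exp(-(r - 0.35 * R)^2 / (2 * (0.05 * R)^2))
      l1pat <- (rim + shell) * disk
      l1n <- l1pat / max(l1pat)
      nP <- 25L
      px <- ctr + stats::runif(nP, -0.75, 0.75) * R
      py <- ctr + stats::runif(nP, -0.75, 0.75) * R
      puncta <- matrix(0, sz, sz)
      for (p in seq_len(nP))
        puncta <- puncta +
          exp(-((matrix(g$x, sz, sz) - px[p])^2 +
                (matrix(g$y, sz, sz) - py[p])^2) / (2 * (0.05 * R)^2))
      b1pat <- (1 - l1n) * (0.35 + puncta) * disk
    } else {
      f <- smoothField(sz)
      l1pat <- f * disk
      b1pat <- f * disk
    }
    lambda <- spec$snr^2
    noisy <- function(pat) {
      pk <- max(pat)
      if (pk == 0) pk <- 1
      x <- stats::rpois(length(pat), lambda * pat / pk) +
        abs(stats::rnorm(length(pat), 0, 0.5))
      matrix(x, nrow(pat), ncol(pat))
    }
    dna <- noisy(disk * 1 + 0.02)
    NucleusImage(noisy(l1pat), noisy(b1pat), dna = dna)
  })
}
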