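#' @include io.R
NULL

#' Balance a raw contact matrix by iterative proportional fitting
#'
#' Row/column equalization of the good-bin submatrix (each good bin's
#' marginal is driven to the mean marginal), accepted as a lightweight
#' stand-alone normalization for raw input; matrices balanced upstream
#' can be supplied directly to every statistic.
#'
#' @param m A raw [ContactMatrix-class].
#' @param maxIter Maximum iterations (default 50).
#' @param tol Convergence tolerance on the maximum relative deviation of
#'   good-bin marginals from their mean (default 1e-5).
#' @return A balanced [ContactMatrix-class].
#' @export
iceBalance <- function(m, maxIter = 50L, tol = 1e-5) {
  x <- counts(m)
  n <- nrow(x)
  good <- setdiff(seq_len(n), badBins(m))
  if (!length(good)) stop("all bins are bad")
  b <- rep(1, n)
  for (it in seq_len(maxIter)) {
    w <- x / outer(b, b)
    s <- rowSums(w[, good, drop = FALSE], na.rm = TRUE)
    s[-good] <- NA
    mu <- mean(s[good])
    if (mu == 0) stop("matrix has no counts on good bins")
    rel <- s[good] / mu
    if (max(abs(rel - 1)) < tol) break
    b[good] <- b[good] * sqrt(rel)
  }
  w <- x / outer(b, b)
  ContactMatrix(m@chrom, m@binSize, w, "balanced", badBins(m))
}

#' Mean contact by genomic separation
#'
#' For each separation `s` (in bins, starting at 0), the mean of counts
#' over all good-bin pairs at that separation; the distance-decay
#' expectation behind O/E normalization. No monotone smoothing is
#' applied.
#'
#' @param m A [ContactMatrix-class].
#' @return Numeric vector of length `n`, entry `s + 1` holding the mean
#'   at separation `s`.
#' @export
expectedByDistance <- function(m) {
  x <- counts(m)
  n <- nrow(x)
  good <- rep(TRUE, n)
  good[badBins(m)] <- FALSE
  if (!any(good)) stop("all bins are bad")
  vapply(0:(n - 1L), function(s) {
    i <- seq_len(n - s)
    j <- i + s
    ok <- good[i] & good[j]
    if (!any(ok)) return(NA_real_)
    mean(x[cbind(i[ok], j[ok])], na.rm = TRUE)
  }, numeric(1))
}

#' Observed-over-expected contact matrix
#'
#' Divides each pixel by the mean contact at its separation; bad bins are
#' masked. A zero expectation at a separation holding non-zero counts is
#' masked with a warning.
#'
#' @param m A [ContactMatrix-class] (raw or balanced).
#' @return A [ContactMatrix-class] with normalization `"oe"`.
#' @export
observedOverExpected <- function(m) {
  x <- counts(m)
  n <- nrow(x)
  ev <- expectedByDistance(m)
  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  e <- matrix(ev[sep + 1L], n, n)
  zero <- !is.na(e) & e == 0
  if (any(zero & !is.na(x) & x != 0))
    warning("zero expectation at a populated separation; pixels masked")
  e[zero] <- NA
  oe <- x / e
  if (length(badBins(m))) {
    oe[badBins(m), ] <- NA
    oe[, badBins(m)] <- NA
  }
  ContactMatrix(m@chrom, m@binSize, oe, "oe", badBins(m))
}

#' Pairwise Pearson correlation of O/E rows
#'
#' The correlation heatmap of compartment analysis: entry (i, j) is the
#' Pearson correlation of bins i and j's O/E contact profiles over
#' mutually good bins. Constant rows are masked.
#'
#' @param oe An O/E [ContactMatrix-class].
#' @return A symmetric numeric matrix with unit diagonal on good bins.
#' @export
correlationMatrix <- function(oe) {
  x <- counts(oe)
  n <- nrow(x)
  good <- setdiff(seq_len(n), badBins(oe))
  if (length(good) < 3L) stop("need at least 3 good bins")
  cc <- suppressWarnings(cor(x, use = "pairwise.complete.obs"))
  sds <- apply(x, 2L, stats::sd, na.rm = TRUE)
  constant <- which(is.na(sds) | sds == 0)
  cc[constant, ] <- NA
  cc[, constant] <- NA
  diag(cc)[setdiff(good, constant)] <- 1
  cc[badBins(oe), ] <- NA
  cc[, badBins(oe)] <- NA
  cc
}

#' Leading eigenvector of the contact correlation matrix
#'
#' The compartment eigenvector (PC1 analogue): the leading eigenvector of
#' the good-bin correlation matrix, re-embedded with missing values at
#' bad bins. The global sign is chosen so the track correlates
#' non-negatively with the anchor (by default a B1 density track, so
#' positive values mean the A-like state); a zero anchor correlation
#' leaves the sign as computed and flags the orientation ambiguous.
#'
#' @param corr Correlation matrix from [correlationMatrix()].
#' @param anchor A [BinnedTrack-class] on the same bins (single
#'   chromosome), used only to fix the sign.
#' @param chrom Chromosome of `anchor` to use; defaults to its first.
#' @return An [EigenTrack-class].
#' @export
compartmentEigenvector <- function(corr, anchor, chrom = NULL) {
  if (is.null(chrom)) chrom <- seqnames(anchor@genome)[1L]
  av <- anchor@values[[chrom]]
  n <- nrow(corr)
  if (length(av) != n)
    stop("anchor track and correlation matrix disagree on bin count")
  good <- which(!apply(corr, 1L, function(r) all(is.na(r))))
  if (length(good) < 3L) stop("need at least 3 good bins")
  sub <- corr[good, good, drop = FALSE]
  sub[is.na(sub)] <- 0
  vals <- unique(as.vector(sub))
  if (length(vals) <= 1L)
    stop("degenerate spectrum: correlation matrix is constant")
  es <- eigen(sub, symmetric = TRUE)
  v1 <- es$vectors[, 1L]
  varShare <- es$values[1L] / sum(pmax(es$values, 0))
  ev <- rep(NA_real_, n)
  ev[good] <- v1
  r <- suppressWarnings(cor(ev, av, use = "pairwise.complete.obs"))
  orientation <- "anchored"
  if (is.na(r) || r == 0) {
    orientation <- "ambiguous"
  } else if (r < 0) {
    ev <- -ev
  }
  sl <- stats::setNames(seqlengths(anchor@genome)[[chrom]], chrom)
  gen <- Seqinfo(seqnames = chrom, seqlengths = sl)
  new("EigenTrack",
      BinnedTrack(gen, anchor@binSize, list(ev) |> stats::setNames(chrom),
                  "eigenvector"),
      orientation = orientation, varExplained = varShare)
}

# coerce an eigenvector argument to a plain numeric vector
evValues <- function(ev) {
  if (is(ev, "BinnedTrack")) unlist(ev@values, use.names = FALSE)
  else as.numeric(ev)
}

#' Saddle plot and compartment strength
#'
#' Bins are ranked by eigenvector value (ascending: most B-like first)
#' and cut into `nQuantiles` equal-occupancy groups; each saddle cell is
#' the mean O/E over cis bin pairs in that pair of groups at separation
#' at least `minSeparation` bins. Compartment strength is
#' `(AA + BB) / (AB + BA)` over the mean values of the extreme-corner
#' cells, where the corners span the extreme `cornerFraction` of
#' quantiles.
#'
#' @param oe An O/E [ContactMatrix-class].
#' @param ev An [EigenTrack-class] (or numeric vector) on the same bins.
#' @param nQuantiles Number of quantile groups (default 50); reduced
#'   with a warning when there are fewer good bins than groups.
#' @param cornerFraction Fraction of quantiles in each corner
#'   (default 0.2).
#' @param minSeparation Minimum separation in bins (default 2): the
#'   near-diagonal otherwise swamps the compartment signal.
#' @return A [SaddleResult-class].
#' @export
saddleStrength <- function(oe, ev, nQuantiles = 50L, cornerFraction = 0.2,
                           minSeparation = 2L) {
  x <- counts(oe)
  n <- nrow(x)
  e <- evValues(ev)
  if (length(e) != n) stop("eigenvector and matrix disagree on bin count")
  good <- which(is.finite(e))
  good <- setdiff(good, badBins(oe))
  if (length(good) < 2L) stop("too few good bins")
  if (length(good) < nQuantiles) {
    warning("fewer good bins than quantiles; reducing to ", length(good))
    nQuantiles <- length(good)
  }
  rk <- rank(e[good], ties.method = "first")
  grp <- ceiling(rk * nQuantiles / length(good))
  g <- rep(NA_integer_, n)
  g[good] <- grp
  idx <- which(!is.na(x) & abs(row(x) - col(x)) >= minSeparation,
               arr.ind = TRUE)
  gi <- g[idx[, 1L]]; gj <- g[idx[, 2L]]
  ok <- !is.na(gi) & !is.na(gj)
  vals <- x[idx][ok]; gi <- gi[ok]; gj <- gj[ok]
  saddle <- matrix(NA_real_, nQuantiles, nQuantiles)
  if (length(vals)) {
    agg <- tapply(vals, list(factor(gi, levels = seq_len(nQuantiles)),
                             factor(gj, levels = seq_len(nQuantiles))),
                  mean)
    saddle[] <- agg
  }
  ncorner <- max(1L, round(cornerFraction * nQuantiles))
  lo <- seq_len(ncorner)                        # most B-like quantiles
  hi <- nQuantiles - ncorner + seq_len(ncorner) # most A-like quantiles
  AA <- mean(saddle[hi, hi], na.rm = TRUE)
  BB <- mean(saddle[lo, lo], na.rm = TRUE)
  AB <- mean(saddle[lo, hi], na.rm = TRUE)
  BA <- mean(saddle[hi, lo], na.rm = TRUE)
  new("SaddleResult", saddle = saddle, nQuantiles = as.integer(nQuantiles),
      cornerFraction = cornerFraction, strength = (AA + BB) / (AB + BA))
}

# label each bin of a matrix by the compartment covering its midpoint
binLabels <- function(m, compartments) {
  n <- nrow(counts(m))
  mid <- (seq_len(n) - 1) * m@binSize + m@binSize / 2
  pts <- GRanges(m@chrom, IRanges(round(mid), width = 1L))
  hits <- findOverlaps(pts, regions(compartments), ignore.strand = TRUE)
  lab <- rep(NA_character_, n)
  lab[S4Vectors::queryHits(hits)] <-
    as.character(mcols(regions(compartments))$label[
      S4Vectors::subjectHits(hits)])
  lab
}

#' Homotypic/heterotypic contact segregation index
#'
#' Each bin inherits the label of the compartment covering its midpoint;
#' bins covered by no compartment are excluded. The homotypic mean pools
#' contacts between same-label bin pairs of both classes (B1.B1 and
#' L1.L1), the heterotypic mean covers cross-label pairs (B1.L1), both at
#' separation at least `minSeparation` bins; the index is their ratio,
#' per chromosome, with a genome summary averaging autosomes only.
#'
#' @param matrices A [ContactMatrix-class] or list of them (one per
#'   chromosome). Supply raw/balanced matrices for the contact-frequency
#'   index, or pass each through [observedOverExpected()] first for the
#'   distance-normalized variant.
#' @param compartments A two-class [CompartmentSet-class].
#' @param minSeparation Minimum separation in bins (default 2).
#' @param excludeChroms Chromosomes left out of the genome summary
#'   (default the sex chromosomes).
#' @return A [SegregationResult-class].
#' @export
segregationIndex <- function(matrices, compartments, minSeparation = 2L,
                             excludeChroms = c("chrX", "chrY")) {
  if (is(matrices, "ContactMatrix")) matrices <- list(matrices)
  labset <- compartments@alphabet
  if (length(labset) != 2L)
    stop("compartments must carry exactly two label classes")
  rows <- list()
  for (m in matrices) {
    lab <- binLabels(m, compartments)
    x <- counts(m)
    n <- nrow(x)
    usable <- !is.na(lab)
    usable[badBins(m)] <- FALSE
    if (length(unique(lab[usable])) < 2L) {
      warning("chromosome ", m@chrom,
              " has a single label class; skipped")
      next
    }
    ii <- row(x); jj <- col(x)
    keep <- abs(ii - jj) >= minSeparation & usable[ii] & usable[jj] &
      !is.na(x)
    same <- keep & lab[ii] == lab[jj]
    cross <- keep & lab[ii] != lab[jj]
    hom <- mean(x[same])
    het <- mean(x[cross])
    rows[[m@chrom]] <- data.frame(chrom = m@chrom, homotypic = hom,
                                  heterotypic = het, index = hom / het,
                                  stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no chromosome yielded a segregation index")
  perChrom <- do.call(rbind, rows)
  rownames(perChrom) <- NULL
  auto <- !(perChrom$chrom %in% excludeChroms)
  new("SegregationResult", perChrom = perChrom,
      summary = mean(perChrom$index[auto]),
      excluded = intersect(excludeChroms, perChrom$chrom))
}

#' Trans (inter-chromosomal) segregation of labeled bins
#'
#' Homotypic over heterotypic mean contact frequency across a
#' rectangular inter-chromosomal contact block. No distance
#' normalization is applied: chromosomes have no genomic separation, so
#' raw (or balanced) trans frequencies are compared directly.
#'
#' @param x Numeric matrix of trans contacts, rows belonging to one
#'   chromosome and columns to another.
#' @param rowLabels,colLabels Character labels per row/column bin; `NA`
#'   bins are excluded.
#' @return A list with `homotypic`, `heterotypic` and `index`.
#' @export
transSegregation <- function(x, rowLabels, colLabels) {
  if (nrow(x) != length(rowLabels) || ncol(x) != length(colLabels))
    stop("label vectors must match the matrix dimensions")
  ok <- outer(!is.na(rowLabels), !is.na(colLabels), "&") & !is.na(x)
  same <- outer(rowLabels, colLabels, "==") & ok
  cross <- ok & !same
  if (!any(same, na.rm = TRUE) || !any(cross, na.rm = TRUE))
    stop("need both homotypic and heterotypic trans pixels")
  hom <- mean(x[which(same)])
  het <- mean(x[which(cross)])
  list(homotypic = hom, heterotypic = het, index = hom / het)
}

#' Compartment-label conservation across samples
#'
#' Per bin, each sample's label is the sign of its eigenvector; bins
#' missing (or exactly zero) in any sample are excluded. A bin is
#' consistent in at least `k` samples when its modal label occurs in
#' `>= k` of them, and invariant when all samples agree. The chance level
#' is a permutation null that independently permutes each sample's labels
#' across bins, preserving each sample's A/B marginal.
#'
#' @param evs List of [EigenTrack-class]s (or numeric vectors) sharing a
#'   binning; at least 2.
#' @param k Consistency threshold in samples.
#' @param nPerm Number of permutations for the null (default 100).
#' @param seed Seed for the permutation null.
#' @return A list: `consistentFraction`, `invariantFraction`,
#'   `nullConsistent`, `nullInvariant`, `nSamples`, `nBins`, `nPerm`,
#'   `seed`.
#' @export
conservationAcrossSamples <- function(evs, k, nPerm = 100L, seed = 1L) {
  if (length(evs) < 2L) stop("need at least 2 samples")
  vs <- lapply(evs, evValues)
  nb <- unique(lengths(vs))
  if (length(nb) != 1L) stop("samples must share binning")
  labs <- do.call(cbind, lapply(vs, sign))
  labs[labs == 0] <- NA
  ok <- rowSums(is.na(labs)) == 0L
  if (!any(ok)) stop("no bin observed in all samples")
  labs <- labs[ok, , drop = FALSE]
  S <- ncol(labs)
  if (k > S) stop("k cannot exceed the number of samples")
  fracs <- function(mat) {
    npos <- rowSums(mat > 0)
    modal <- pmax(npos, S - npos)
    c(consistent = mean(modal >= k), invariant = mean(modal == S))
  }
  obs <- fracs(labs)
  nullmat <- withSeed(seed, {
    vapply(seq_len(nPerm), function(p) {
      perm <- apply(labs, 2L, sample)
      fracs(perm)
    }, numeric(2))
  })
  list(consistentFraction = unname(obs["consistent"]),
       invariantFraction = unname(obs["invariant"]),
       nullConsistent = mean(nullmat["consistent", ]),
       nullInvariant = mean(nullmat["invariant", ]),
       nSamples = S, nBins = nrow(labs), nPerm = nPerm, seed = seed)
}
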