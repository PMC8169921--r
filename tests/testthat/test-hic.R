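test_that("expected-by-distance returns the generating decay profile", {
  n <- 60L
  f <- 100 / (1 + (0:(n - 1)))
  x <- outer(seq_len(n), seq_len(n),
             function(i, j) f[abs(i - j) + 1L])
  m <- ContactMatrix("chr1", 100000L, x, badBins = integer(0))
  expect_equal(expectedByDistance(m), f)

  const <- ContactMatrix("chr1", 100000L, matrix(3, n, n),
                         badBins = integer(0))
  expect_equal(expectedByDistance(const), rep(3, n))
})

test_that("expected-by-distance recovers a Poisson-sampled decay", {
  n <- 150L
  P <- 200 / (1 + (0:(n - 1)))
  E <- outer(seq_len(n), seq_len(n),
             function(i, j) P[abs(i - j) + 1L])
  set.seed(12)
  ut <- upper.tri(E, diag = TRUE)
  x <- matrix(0, n, n); x[ut] <- rpois(sum(ut), E[ut])
  x <- x + t(x) - diag(diag(x))
  got <- expectedByDistance(ContactMatrix("chr1", 1e5L, x,
                                          badBins = integer(0)))
  npairs <- n - (0:(n - 1))
  se <- sqrt(P / npairs)
  z <- abs(got - P) / se
  expect_gt(mean(z <= 3), 0.95)
  expect_true(all(z <= 5))
})

test_that("O/E normalization is exact on its own profile and scale-free", {
  n <- 40L
  f <- 50 / (1 + (0:(n - 1)))
  x <- outer(seq_len(n), seq_len(n), function(i, j) f[abs(i - j) + 1L])
  m <- ContactMatrix("chr1", 1e5L, x, badBins = integer(0))
  oe <- observedOverExpected(m)
  expect_equal(unname(counts(oe)), matrix(1, n, n))
  m2 <- ContactMatrix("chr1", 1e5L, 2 * x, badBins = integer(0))
  expect_equal(counts(observedOverExpected(m2)), counts(oe))
})

test_that("planted plaid O/E reproduces the affinity contrast", {
  sim <- simulateRepeatGenome(SyntheticGenomeSpec(nChroms = 1L, seed = 2))
  spec <- SyntheticHiCSpec(seed = 2)
  m <- simulateContactMatrix(sim$truth, spec, chrom = "chr1")
  oe <- counts(observedOverExpected(m))
  n <- nrow(oe)
  mids <- GRanges("chr1", IRanges((seq_len(n) - 1L) * 100000L + 50000L,
                                  width = 1L))
  hits <- findOverlaps(mids, regions(sim$truth))
  lab <- rep(NA_character_, n)
  lab[queryHits(hits)] <-
    mcols(regions(sim$truth))$label[subjectHits(hits)]
  same <- outer(lab, lab, "==")
  sep <- abs(outer(seq_len(n), seq_len(n), "-")) >= 2
  ratio <- mean(oe[same & sep], na.rm = TRUE) /
    mean(oe[!same & sep], na.rm = TRUE)
  expect_lt(abs(ratio - spec$aHom / spec$aHet), 0.1 * spec$aHom / spec$aHet)
})

test_that("correlation matrix separates a two-block checkerboard", {
  lab <- rep(c("A", "B"), 4)                 # 8-bin toy, interleaved
  oe <- plaidOE(lab)
  cc <- correlationMatrix(oe)
  expect_equal(dim(cc), c(8L, 8L))
  expect_equal(diag(cc), rep(1, 8))
  expect_true(all(abs(cc - t(cc)) < 1e-12))
  same <- outer(lab, lab, "==")
  expect_true(all(cc[same] > 0))
  expect_true(all(cc[!same] < 0))
})

test_that("constant O/E rows are masked in the correlation matrix", {
  x <- matrix(rnorm(100, 10), 10, 10)
  x <- (x + t(x)) / 2
  x[3, ] <- 5; x[, 3] <- 5
  cc <- correlationMatrix(ContactMatrix("chr1", 1e5L, abs(x),
                                        badBins = integer(0)))
  expect_true(all(is.na(cc[3, ])))
})

test_that("the eigenvector recovers exact two-block structure", {
  lab <- rep(c("A", "B"), each = 10)
  corr <- outer(lab, lab, function(a, b) ifelse(a == b, 1, -1))
  anchor <- coverageTrack(ifelse(lab == "A", 0.08, 0.01))
  ev <- compartmentEigenvector(corr, anchor)
  v <- trackValues(ev, "chr1")
  expect_equal(sign(v), ifelse(lab == "A", 1, -1))
  expect_equal(ev@orientation, "anchored")

  # negating the anchor flips every sign
  ev2 <- compartmentEigenvector(corr,
    coverageTrack(0.1 - ifelse(lab == "A", 0.08, 0.01)))
  expect_equal(trackValues(ev2, "chr1"), -v)

  expect_error(compartmentEigenvector(matrix(1, 20, 20), anchor),
               "degenerate")
})

test_that("saddle strength matches the trivial and planted cases", {
  n <- 100L
  uni <- ContactMatrix("chr1", 1e5L, matrix(1, n, n), "oe",
                       badBins = integer(0))
  expect_equal(strength(saddleStrength(uni, rnorm(n))), 1)

  lab <- rep(rep(c("A", "B"), 10), each = 10)
  oe <- plaidOE(lab, 2, 0.5, 1e5L)
  ev <- ifelse(lab == "A", 1, -1) + seq_along(lab) * 1e-9
  sad <- saddleStrength(oe, ev, nQuantiles = 50L)
  expect_equal(strength(sad), 4.0, tolerance = 0.05)
  # positive scaling leaves the ratio untouched
  oe3 <- ContactMatrix("chr1", 1e5L, 3 * counts(oe), "oe",
                       badBins = integer(0))
  expect_equal(strength(saddleStrength(oe3, ev)), strength(sad))
})

test_that("segregation index matches brute force on a 12-bin toy", {
  lab <- rep(c("B1-rich", "L1-rich"), each = 6)
  same <- outer(lab, lab, "==")
  x <- matrix(1, 12, 12); x[same] <- 2
  m <- ContactMatrix("chr1", 1e6L, x, badBins = integer(0))
  cs <- CompartmentSet(GRanges("chr1", IRanges(c(1, 6000001), width = 6e6),
                               label = c("B1-rich", "L1-rich")))
  res <- segregationIndex(m, cs, excludeChroms = character(0))
  expect_equal(segIndex(res), 2.0)
  expect_equal(segIndex(res), bruteSegIndex(x, lab))

  uni <- ContactMatrix("chr1", 1e6L, matrix(5, 12, 12),
                       badBins = integer(0))
  expect_equal(segIndex(segregationIndex(uni, cs,
                                         excludeChroms = character(0))), 1)

  # pooling is symmetric under label swap
  swapped <- CompartmentSet(
    GRanges("chr1", IRanges(c(1, 6000001), width = 6e6),
            label = c("L1-rich", "B1-rich")))
  expect_equal(segIndex(segregationIndex(m, swapped,
                                         excludeChroms = character(0))),
               segIndex(res))
})

test_that("single-class chromosomes are skipped with a warning", {
  x <- matrix(1, 12, 12)
  m <- ContactMatrix("chr9", 1e6L, x, badBins = integer(0))
  cs <- CompartmentSet(GRanges("chr9", IRanges(1, 12e6), label = "B1-rich"),
                       alphabet = c("B1-rich", "L1-rich"))
  expect_warning(expect_error(segregationIndex(m, cs), "no chromosome"),
                 "single label")
})

test_that("sex chromosomes are excluded from the genome summary", {
  lab <- rep(c("B1-rich", "L1-rich"), each = 6)
  same <- outer(lab, lab, "==")
  x <- matrix(1, 12, 12); x[same] <- 2
  mk <- function(ch, xx) ContactMatrix(ch, 1e6L, xx, badBins = integer(0))
  csFor <- function(ch) CompartmentSet(
    GRanges(ch, IRanges(c(1, 6000001), width = 6e6),
            label = c("B1-rich", "L1-rich")))
  cs <- CompartmentSet(
    GRanges(rep(c("chr1", "chrX"), each = 2),
            IRanges(rep(c(1, 6000001), 2), width = 6e6),
            label = rep(c("B1-rich", "L1-rich"), 2)))
  xX <- matrix(1, 12, 12); xX[same] <- 10     # extreme X should not count
  res <- segregationIndex(list(mk("chr1", x), mk("chrX", xX)), cs)
  expect_equal(segIndex(res), 2.0)
  expect_equal(res@excluded, "chrX")
  expect_equal(nrow(res@perChrom), 2L)
})

test_that("iterative balancing equalizes good-bin marginals", {
  set.seed(9)
  n <- 50L
  b <- runif(n, 0.3, 3)
  base <- outer(seq_len(n), seq_len(n),
                function(i, j) 10 / (1 + abs(i - j)))
  x <- round(base * outer(b, b) * 10)
  m <- ContactMatrix("chr1", 1e5L, x)
  bal <- iceBalance(m)
  good <- setdiff(seq_len(n), badBins(bal))
  rs <- rowSums(counts(bal)[good, good])
  expect_lt(max(abs(rs / mean(rs) - 1)), 1e-3)
  expect_equal(bal@normalization, "balanced")
})

test_that("correlation structure is equivariant under joint permutation", {
  truth <- alternatingCompartments(blockLen = 2e6, nBlocks = 10L,
                                   labels = c("B1-rich", "L1-rich"))
  m <- simulateContactMatrix(truth, SyntheticHiCSpec(seed = 6),
                             chrom = "chr1", chromLength = 20e6)
  oe <- observedOverExpected(m)
  cc <- correlationMatrix(oe)
  set.seed(10)
  p <- sample(nrow(cc))
  ccPerm <- correlationMatrix(
    ContactMatrix("chr1", 1e5L, counts(oe)[p, p], "oe",
                  badBins = integer(0)))
  expect_equal(ccPerm, cc[p, p], tolerance = 1e-10)
})

test_that("conservation fractions are exact for identical samples", {
  v <- sign(rnorm(500))
  res <- conservationAcrossSamples(list(v, v, v), k = 2)
  expect_equal(res$consistentFraction, 1)
  expect_equal(res$invariantFraction, 1)
  expect_error(conservationAcrossSamples(list(v, rnorm(10)), k = 2),
               "share binning")
  expect_error(conservationAcrossSamples(list(v), k = 1), "at least 2")
})

test_that("the permutation null matches the fair-coin binomial form", {
  set.seed(14)
  evs <- lapply(1:21, function(i) sample(c(-1, 1), 4000, replace = TRUE))
  res <- conservationAcrossSamples(evs, k = 16, nPerm = 60, seed = 3)
  closed <- 2 * pbinom(15, 21, 0.5, lower.tail = FALSE)
  expect_lt(abs(res$nullConsistent - closed), 0.01)
  expect_lt(res$nullInvariant, 1e-4)
  expect_lt(abs(res$consistentFraction - closed), 0.01)
})

test_that("segregation and saddle respond monotonically to affinity", {
  truth <- alternatingCompartments(blockLen = 1.5e6, nBlocks = 16L,
                                   labels = c("B1-rich", "L1-rich"))
  sVals <- c(); stVals <- c()
  for (aH in c(1.0, 1.8, 3.0)) {
    m <- simulateContactMatrix(
      truth, SyntheticHiCSpec(aHom = aH, aHet = 1, seed = 20),
      chrom = "chr1", chromLength = 24e6)
    oe <- observedOverExpected(m)
    sVals <- c(sVals, segIndex(segregationIndex(oe, truth,
                                                excludeChroms = character(0))))
    anchor <- coverageTrack(rep(rep(c(0.08, 0.01), 8), each = 15))
    ev <- compartmentEigenvector(correlationMatrix(oe), anchor)
    stVals <- c(stVals, strength(saddleStrength(oe, ev)))
  }
  expect_true(all(diff(sVals) > 0))
  expect_true(all(diff(stVals) > 0))
})

test_that("trans segregation compares inter-chromosomal pixels directly", {
  rowLab <- c("B1-rich", "B1-rich", "L1-rich", NA)
  colLab <- c("B1-rich", "L1-rich", "L1-rich")
  x <- matrix(1, 4, 3)
  x[1:2, 1] <- 3; x[3, 2:3] <- 3          # homotypic pixels at 3
  res <- transSegregation(x, rowLab, colLab)
  expect_equal(res$homotypic, 3)
  expect_equal(res$heterotypic, 1)
  expect_equal(res$index, 3)
  expect_error(transSegregation(x, colLab, colLab), "dimensions")
  expect_error(transSegregation(matrix(1, 2, 2), c("A", "A"), c("A", "A")),
               "heterotypic")
})
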