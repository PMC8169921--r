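test_that("RepeatMasker .out coordinates convert from 1-based inclusive", {
  g <- tinyGenome(c(chr1 = 100000L))
  f <- writeTempLines(c(
    "   SW   perc perc perc  query     position in query     matching repeat",
    "score   div. del. ins.  sequence  begin end (left)      repeat class/family begin end (left) ID",
    "",
    "  463   11.2  0.0  0.0  chr1   1001  1500 (98500) +  L1Md_T  LINE/L1  1  500  (5900)  1"))
  ann <- readRepeatMasker(f, g)
  expect_equal(start(ann), 1001L)   # 0-based 1000
  expect_equal(end(ann), 1500L)
  expect_equal(width(ann), 500L)
  expect_equal(ann$subfamily, "L1Md_T")
})

test_that("BED repeat records pass through and filters apply", {
  g <- tinyGenome(c(chr1 = 100000L))
  f <- writeTempLines(c("chr1\t0\t6500\tL1Md_T",
                        "chr1\t7000\t7300\tB1_Mus1",
                        "chrUn\t0\t100\tL1Md_A"))
  expect_warning(ann <- readRepeatMasker(f, g), "1 record")
  expect_equal(length(ann), 2L)
  expect_equal(width(ann)[ann$subfamily == "L1Md_T"], 6500L)
  l1only <- suppressWarnings(
    readRepeatMasker(f, g, subfamilies = "L1", prefix = TRUE))
  expect_equal(unique(l1only$subfamily), "L1Md_T")
})

test_that("malformed lines are reported with their line number", {
  g <- tinyGenome(c(chr1 = 100000L))
  f <- writeTempLines(c("chr1\t0\t6500\tL1Md_T", "chr1\tnot_a_number"))
  expect_error(readRepeatMasker(f, g), "line 2")
})

test_that("binCoverage computes union coverage fractions per bin", {
  g <- tinyGenome(c(chr1 = 30000L))
  ann <- repeatGR("chr1", c(1L, 10001L, 20001L, 24001L),
                  c(10000L, 15000L, 26000L, 28000L),
                  rep("L1Md_T", 4), g)
  tr <- binCoverage(ann, g, 10000L, "L1", prefix = TRUE)
  v <- trackValues(tr, "chr1")
  expect_equal(v[1], 1.0)          # full bin
  expect_equal(v[2], 0.5)          # half bin
  expect_equal(v[3], 0.8)          # union of 20-26k and 24-28k = 8 kb
  expect_s4_class(tr, "BinnedTrack")
  expect_equal(valueKind(tr), "coverage_fraction")
})

test_that("coverage is conserved and consistent across bin refinement", {
  g <- tinyGenome(c(chr1 = 95000L))   # deliberately not a bin multiple
  set.seed(42)
  s <- sort(sample(1:90000, 30))
  ann <- repeatGR("chr1", s, pmin(s + sample(200:3000, 30, TRUE), 95000L),
                  rep("L1Md_T", 30), g)
  merged <- reduce(ann, ignore.strand = TRUE)
  tr <- binCoverage(ann, g, 10000L, "L1", prefix = TRUE)
  v <- trackValues(tr, "chr1")
  widths <- c(rep(10000, 9), 5000)   # terminal partial bin has true width
  expect_equal(sum(v * widths), sum(width(merged)))
  # block-averaging: coverage at 10 kb equals the width-weighted mean of
  # the five 2-kb sub-bins
  fine <- trackValues(binCoverage(ann, g, 2000L, "L1", prefix = TRUE),
                      "chr1")
  coarse <- vapply(seq_along(v), function(i)
    mean(fine[(5 * (i - 1) + 1):min(5 * i, length(fine))]), numeric(1))
  expect_equal(v, coarse, tolerance = 1e-12)
})

test_that("trackCorrelation matches its contracts", {
  set.seed(1)
  a <- coverageTrack(runif(100))
  expect_equal(trackCorrelation(a, a), 1.0)
  b <- coverageTrack(1 - trackValues(a, "chr1"))
  expect_equal(trackCorrelation(a, b), -1.0)
  short <- coverageTrack(c(0.1, NA, NA, NA, 0.3, NA, NA, NA, NA, NA))
  short2 <- coverageTrack(c(0.2, NA, NA, NA, 0.1, NA, NA, NA, NA, NA))
  expect_error(trackCorrelation(short, short2), "fewer than 3")
  # independent tracks decorrelate at large n
  set.seed(7)
  x <- coverageTrack(runif(10000)); y <- coverageTrack(runif(10000))
  expect_lt(abs(trackCorrelation(x, y)), 0.05)
  expect_error(trackCorrelation(a, coverageTrack(runif(50))),
               "genome and bin size")
})

test_that("intervalRepeatContent matches arithmetic and brute force", {
  g <- tinyGenome(c(chr1 = 2000000L))
  ann <- repeatGR("chr1", c(1L, 500001L), c(100000L, 590000L),
                  c("L1Md_T", "L1Md_A"), g)
  iv <- GRanges("chr1", IRanges(c(1, 1000001, 1), width = c(100000, 100000, 1000000)))
  got <- intervalRepeatContent(ann, iv, "L1", prefix = TRUE)
  expect_equal(got[1], 1.0)     # fully tiled
  expect_equal(got[2], 0.0)     # empty
  expect_equal(got[3], 0.19)    # 190 kb merged in 1 Mb
  # brute-force oracle on a messy overlapping case
  es <- c(10L, 50L, 45L, 200L); ee <- c(60L, 120L, 55L, 300L)
  ann2 <- repeatGR("chr1", es, ee, rep("L1Md_T", 4), g)
  iv2 <- GRanges("chr1", IRanges(c(1L, 40L, 250L), c(100L, 260L, 305L)))
  expect_equal(intervalRepeatContent(ann2, iv2, "L1", prefix = TRUE),
               bruteIntervalContent(es, ee, start(iv2), end(iv2)))
})

test_that("intervalRepeatContent is invariant under element splitting", {
  g <- tinyGenome(c(chr1 = 100000L))
  whole <- repeatGR("chr1", 1000L, 9999L, "L1Md_T", g)
  pieces <- repeatGR("chr1", c(1000L, 4000L, 7500L),
                     c(3999L, 7499L, 9999L), rep("L1Md_T", 3), g)
  iv <- GRanges("chr1", IRanges(c(1L, 2000L), c(50000L, 8000L)))
  expect_equal(intervalRepeatContent(whole, iv, "L1", prefix = TRUE),
               intervalRepeatContent(pieces, iv, "L1", prefix = TRUE))
})

test_that("interval shuffling preserves lengths and is reproducible", {
  g <- tinyGenome(c(chr1 = 50000000L, chr2 = 30000000L))
  set.seed(3)
  s <- sort(sample(1:45000000, 40))
  iv <- GRanges(rep(c("chr1", "chr2"), each = 20),
                IRanges(c(s[1:20], s[1:20] %/% 2),
                        width = sample(10000:400000, 40)))
  sh1 <- shuffleIntervals(iv, g, seed = 5)
  sh2 <- shuffleIntervals(iv, g, seed = 5)
  expect_identical(start(sh1), start(sh2))
  expect_equal(sort(width(sh1)[as.character(seqnames(sh1)) == "chr1"]),
               sort(width(iv)[as.character(seqnames(iv)) == "chr1"]))
  for (ch in c("chr1", "chr2")) {
    sub <- sh1[as.character(seqnames(sh1)) == ch]
    expect_true(all(start(sub) >= 1), info = ch)
    expect_true(all(end(sub) <= seqlengths(g)[[ch]]))
    expect_equal(length(reduce(sub, min.gapwidth = 0L)), length(sub))
  }
  expect_error(shuffleIntervals(
    GRanges("chr1", IRanges(1, width = 6e7)), g, seed = 1), "chr1")
})

test_that("shuffled-interval repeat content approaches the genome fraction", {
  g <- tinyGenome(c(chr1 = 50000000L))
  # deterministic 20% L1: a 2-kb element every 10 kb
  s <- seq(1L, 50000000L - 10000L, by = 10000L)
  ann <- repeatGR("chr1", s, s + 1999L, rep("L1Md_T", length(s)), g)
  iv <- GRanges("chr1", IRanges(rep(1, 600), width = 50000))
  sh <- shuffleIntervals(iv, g, seed = 11)
  content <- intervalRepeatContent(ann, sh, "L1", prefix = TRUE)
  expect_lt(abs(mean(content) - 0.2), 0.02)
})

test_that("TAD content correlation recovers planted anti-correlation", {
  sim <- simulateRepeatGenome(SyntheticGenomeSpec(
    nChroms = 1L, chromLength = 20e6, seed = 4))
  tads <- regions(sim$truth)       # blocks as stand-in TADs
  res <- tadContentCorrelation(sim$annotation, tads)
  expect_lte(res$r, -0.9)
  expect_true(all(res$contentA >= 0 & res$contentA <= 1))
  flat <- repeatGR("chr1", c(1L, 1000001L), c(200000L, 1200000L),
                   c("L1Md_T", "L1Md_T"), sim$genome)
  sameTads <- GRanges("chr1", IRanges(c(1, 1000001), width = 1000000))
  expect_error(tadContentCorrelation(flat, c(sameTads, sameTads[1])),
               "zero variance|at least 3")
})
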