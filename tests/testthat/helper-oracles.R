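# Brute-force run-scan compartment caller: walks the bin vector once,
# opening a region at each sign change, independent of the rle-based
# implementation under test. Returns data.frame(start, end, sign).
bruteRunScan <- function(v, binSize, chromLen, minSize = 500000) {
  n <- length(v)
  out <- data.frame(start = integer(0), end = integer(0), sgn = integer(0))
  i <- 1L
  while (i <= n) {
    s <- sign(v[i])
    if (is.na(s)) s <- 0
    if (s == 0) { i <- i + 1L; next }
    j <- i
    while (j < n) {
      sj <- sign(v[j + 1L])
      if (is.na(sj)) sj <- 0
      if (sj != s) break
      j <- j + 1L
    }
    startBp <- (i - 1L) * binSize + 1L
    endBp <- min(j * binSize, chromLen)
    if (endBp - startBp + 1 > minSize)
      out <- rbind(out, data.frame(start = startBp, end = endBp, sgn = s))
    i <- j + 1L
  }
  out
}

# Brute-force corner means over labeled bin pairs (the saddle oracle):
# plain double loop, no quantile machinery.
bruteCornerStrength <- function(x, labels, minSeparation = 2L) {
  n <- nrow(x)
  acc <- c(AA = 0, BB = 0, AB = 0)
  cnt <- c(AA = 0, BB = 0, AB = 0)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (abs(i - j) < minSeparation) next
    key <- if (labels[i] == labels[j]) {
      if (labels[i] == "A") "AA" else "BB"
    } else "AB"
    acc[key] <- acc[key] + x[i, j]
    cnt[key] <- cnt[key] + 1
  }
  m <- acc / cnt
  (m[["AA"]] + m[["BB"]]) / (2 * m[["AB"]])
}

# Brute-force segregation index on a toy labeled matrix.
bruteSegIndex <- function(x, labels, minSeparation = 2L) {
  n <- nrow(x)
  hom <- c(); het <- c()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (abs(i - j) < minSeparation || is.na(labels[i]) || is.na(labels[j]))
      next
    if (labels[i] == labels[j]) hom <- c(hom, x[i, j])
    else het <- c(het, x[i, j])
  }
  mean(hom) / mean(het)
}

# Brute-force per-interval union content: per interval, walk elements.
bruteIntervalContent <- function(elemStart, elemEnd, ivStart, ivEnd) {
  vapply(seq_along(ivStart), function(k) {
    bp <- 0L
    covered <- rep(FALSE, ivEnd[k] - ivStart[k] + 1L)
    for (e in seq_along(elemStart)) {
      a <- max(elemStart[e], ivStart[k]); b <- min(elemEnd[e], ivEnd[k])
      if (a <= b) covered[(a:b) - ivStart[k] + 1L] <- TRUE
    }
    sum(covered) / length(covered)
  }, numeric(1))
}
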