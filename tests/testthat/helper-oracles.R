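# Independent brute-force oracles used across the suite. These deliberately
# avoid the code paths they check.

# Type-7 quantile by hand: h = (n-1) p + 1, linear interpolation of order
# statistics.
oracleQuantile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  vapply(p, function(pp) {
    h <- (n - 1) * pp + 1
    lo <- floor(h)
    hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
  }, numeric(1L))
}

# Two-sample KS statistic by exhaustive sweep over every breakpoint.
oracleKS <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t), numeric(1L))))
}

# BH step-up by the definition: q_(i) = min_{j >= i} m * p_(j) / j, capped.
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- rev(cummin(rev(m * p[o] / seq_len(m))))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# BH rejection set by "largest k with p_(k) <= k alpha / m".
oracleBHReject <- function(p, alpha) {
  m <- length(p)
  ps <- sort(p)
  ok <- which(ps <= seq_len(m) * alpha / m)
  if (length(ok) == 0L) return(logical(m))
  p <= ps[max(ok)]
}

# Median-of-ratios size factors from the definition, feature loop.
oracleSizeFactors <- function(cnt) {
  allPos <- apply(cnt, 1L, function(r) all(r > 0))
  sub <- cnt[allPos, , drop = FALSE]
  geo <- apply(sub, 1L, function(r) exp(mean(log(r))))
  vapply(seq_len(ncol(sub)), function(j) median(sub[, j] / geo), numeric(1L))
}

# Spearman rho by hand: average ranks, then textbook Pearson.
oracleSpearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Tiny labelled dataset from a matrix literal.
cdsFrom <- function(m, classes = NULL) {
  m <- as.matrix(m)
  storage.mode(m) <- "integer"
  countsimbench::CountDataSet(m, classLabels = classes)
}
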