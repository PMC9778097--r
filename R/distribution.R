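#' Matched empirical quantiles of two value vectors
#'
#' Computes the (q_x, q_y) pairs of a quantile-quantile comparison at
#' probabilities `i / (n_quantiles + 1)`, `i = 1..n_quantiles`, using the
#' linear-interpolation quantile estimator (type 7).  If two distributions
#' are similar their matched quantiles lie close to the diagonal.
#'
#' @param x,y non-empty numeric vectors (need not have equal length).
#' @param n_quantiles number of probability points (default 99).
#' @return data.frame with columns `prob`, `q_x`, `q_y`; the underlying
#'   vectors are kept in attributes `"x"` and `"y"` for [qqSummary()].
#' @export
qqPoints <- function(x, y, n_quantiles = 99L) {
  if (length(x) == 0L || length(y) == 0L)
    stop("both vectors must be non-empty")
  probs <- seq_len(n_quantiles) / (n_quantiles + 1L)
  out <- data.frame(prob = probs,
                    q_x = quantile(x, probs, names = FALSE, type = 7),
                    q_y = quantile(y, probs, names = FALSE, type = 7))
  attr(out, "x") <- x
  attr(out, "y") <- y
  out
}

#' Summarize a Q-Q comparison
#'
#' Fits an ordinary-least-squares line through the quantile pairs (identical
#' distributions give slope 1, intercept 0), records the maximum absolute
#' quantile deviation over the grid, and the two-sample Kolmogorov-Smirnov
#' statistic of the underlying vectors.
#'
#' @param points output of [qqPoints()] (>= 2 points).
#' @return named list `slope`, `intercept`, `max_abs_deviation`, `ks_stat`,
#'   `n_quantiles`.  A constant `q_x` grid leaves the slope undefined
#'   (`NA`, with a warning).
#' @export
qqSummary <- function(points) {
  if (nrow(points) < 2L) stop("need at least 2 quantile points")
  qx <- points$q_x; qy <- points$q_y
  sxx <- sum((qx - mean(qx))^2)
  if (sxx == 0) {
    warning("degenerate Q-Q comparison: constant q_x, slope undefined")
    slope <- NA_real_; intercept <- NA_real_
  } else {
    slope <- sum((qx - mean(qx)) * (qy - mean(qy))) / sxx
    intercept <- mean(qy) - slope * mean(qx)
  }
  x <- attr(points, "x"); y <- attr(points, "y")
  ks <- if (is.null(x) || is.null(y)) NA_real_ else ksStatistic(x, y)
  list(slope = slope, intercept = intercept,
       max_abs_deviation = max(abs(qy - qx)),
       ks_stat = ks, n_quantiles = nrow(points))
}

# Two-sample KS statistic (max absolute ECDF difference); statistic only,
# no test, ties allowed.
ksStatistic <- function(x, y) {
  unname(suppressWarnings(ks.test(x, y, exact = FALSE))$statistic)
}

#' Descriptive statistics of a count dataset
#'
#' @param object a [CountDataSet-class].
#' @return list with `per_sample` (data.frame: `sample_id`, `library_size`,
#'   `zero_fraction`), `per_feature` (data.frame: `feature_id`, `mean`,
#'   `variance`, `zero_fraction`) and the scalar `overall_zero_fraction`.
#' @export
summaryStats <- function(object) {
  stopifnot(is(object, "CountDataSet"))
  cnt <- counts(object)
  list(
    per_sample = data.frame(
      sample_id = colnames(cnt),
      library_size = colSums(cnt),
      zero_fraction = colMeans(cnt == 0),
      row.names = NULL),
    per_feature = data.frame(
      feature_id = rownames(cnt),
      mean = rowMeans(cnt),
      variance = if (ncol(cnt) > 1L) apply(cnt, 1L, var) else NA_real_,
      zero_fraction = rowMeans(cnt == 0),
      row.names = NULL),
    overall_zero_fraction = mean(cnt == 0))
}

#' Write plot-ready Q-Q pair tables
#'
#' One TSV row per quantile pair per compared sample pair: `input_sample`,
#' `synth_sample`, `prob`, `q_x`, `q_y`.
#'
#' @param qc result of [qqCompare()].
#' @param path output TSV.
#' @export
writeQQTable <- function(qc, path) {
  rows <- lapply(seq_along(qc$points), function(k) {
    cbind(input_sample = qc$pairs$input_sample[k],
          synth_sample = qc$pairs$synth_sample[k],
          qc$points[[k]])
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Dataset-level Q-Q concordance between an input and a synthetic dataset
#'
#' Samples are paired by sorted library size (robust to arbitrary column
#' order): `n_pairs` evenly spaced ranks are taken from each dataset's
#' library-size ordering and compared pair by pair on the `log2(count + 1)`
#' scale (or raw counts).  The dataset-level summary is the mean of each
#' [qqSummary()] field over the compared pairs.
#'
#' @param input,synth [CountDataSet-class] objects.
#' @param n_pairs sample pairs to compare (default 5, capped at the smaller
#'   sample count).
#' @param n_quantiles probability grid size per pair (default 99).
#' @param log2 compare on `log2(count + 1)` scale (default `TRUE`).
#' @return list with `summary` (named numeric vector: mean `slope`,
#'   `intercept`, `max_abs_deviation`, `ks_stat`), `pairs` (data.frame of
#'   per-pair summaries) and `points` (per-pair quantile tables, plot-ready).
#' @export
qqCompare <- function(input, synth, n_pairs = 5L, n_quantiles = 99L,
                      log2 = TRUE) {
  stopifnot(is(input, "CountDataSet"), is(synth, "CountDataSet"))
  n_pairs <- min(as.integer(n_pairs), ncol(input), ncol(synth))
  ordI <- order(colSums(counts(input)))
  ordS <- order(colSums(counts(synth)))
  pickRanks <- function(n) unique(round(seq(1L, n, length.out = n_pairs)))
  selI <- ordI[pickRanks(ncol(input))]
  selS <- ordS[pickRanks(ncol(synth))]
  tf <- if (log2) function(v) log2(v + 1) else identity
  per <- vector("list", length(selI))
  pts <- vector("list", length(selI))
  for (k in seq_along(selI)) {
    p <- qqPoints(tf(counts(input)[, selI[k]]),
                  tf(counts(synth)[, selS[k]]), n_quantiles)
    s <- qqSummary(p)
    per[[k]] <- data.frame(
      input_sample = colnames(input)[selI[k]],
      synth_sample = colnames(synth)[selS[k]],
      slope = s$slope, intercept = s$intercept,
      max_abs_deviation = s$max_abs_deviation, ks_stat = s$ks_stat)
    pts[[k]] <- p
  }
  pairs <- do.call(rbind, per)
  list(summary = c(slope = mean(pairs$slope),
                   intercept = mean(pairs$intercept),
                   max_abs_deviation = mean(pairs$max_abs_deviation),
                   ks_stat = mean(pairs$ks_stat)),
       pairs = pairs, points = pts)
}
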