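#' Counts per million
#'
#' `cpm = count / library_size * 1e6`.  On the log2 scale a prior count is
#' added to both numerator and library size:
#' `log2((count + prior) / (library_size + 2 * prior) * 1e6)`.
#'
#' @param object a [CountDataSet-class] or count matrix.
#' @param log2 return log2-CPM (default `FALSE`).
#' @param prior prior count for the log transform (default 0.5).
#' @return numeric matrix of the same dimensions.
#' @export
cpmCounts <- function(object, log2 = FALSE, prior = 0.5) {
  cnt <- if (is(object, "CountDataSet")) counts(object) else as.matrix(object)
  lib <- colSums(cnt)
  if (any(lib == 0))
    stop("zero library size for sample(s): ",
         paste(head(colnames(cnt)[lib == 0], 5L), collapse = ", "))
  if (log2) {
    base::log2(sweep(cnt + prior, 2L, lib + 2 * prior, "/") * 1e6)
  } else {
    sweep(cnt, 2L, lib, "/") * 1e6
  }
}

#' Per-feature mean and unbiased variance
#'
#' @param object a [CountDataSet-class] or count matrix (>= 2 samples).
#' @param sizeFactors optional per-sample positive factors; counts are
#'   divided by them before the moments are taken.
#' @return data.frame with columns `mean` and `variance` (divisor `n - 1`),
#'   one row per feature.
#' @export
geneMoments <- function(object, sizeFactors = NULL) {
  cnt <- if (is(object, "CountDataSet")) counts(object) else as.matrix(object)
  if (ncol(cnt) < 2L) stop("need at least 2 samples")
  if (!is.null(sizeFactors)) {
    stopifnot(length(sizeFactors) == ncol(cnt), all(sizeFactors > 0))
    cnt <- sweep(cnt, 2L, sizeFactors, "/")
  }
  mu <- rowMeans(cnt)
  v <- rowSums((cnt - mu)^2) / (ncol(cnt) - 1L)
  data.frame(mean = mu, variance = v, row.names = rownames(cnt))
}

#' Method-of-moments negative-binomial dispersion
#'
#' Under the NB parameterization `Var = mu + phi * mu^2`,
#' `phi = max(0, (variance - mean) / mean^2)`; Poisson or under-dispersed
#' features get 0, as does a zero mean.
#'
#' @param mean,variance numeric vectors of per-feature moments.
#' @return numeric vector of dispersions `phi >= 0`.
#' @export
momDispersion <- function(mean, variance) {
  stopifnot(length(mean) == length(variance), all(mean >= 0))
  phi <- ifelse(mean > 0, pmax(0, (variance - mean) / mean^2), 0)
  as.numeric(phi)
}

# Equal-occupancy binning of log(mean) with per-bin medians of `values`.
# Shared by the dispersion and mean-variance trends.
runningMedianTrend <- function(means, values, n_bins = 20L, what = "dispersion") {
  ok <- means > 0 & is.finite(values)
  m <- means[ok]; v <- values[ok]
  if (length(m) < 2L) stop("too few features with positive mean for a trend")
  n_bins <- as.integer(n_bins)
  if (length(m) < n_bins) {
    n_bins <- max(2L, length(m) %/% 2L)
    warning("too few features for requested bins; reduced to ", n_bins)
  }
  lm <- log(m)
  br <- quantile(lm, probs = seq(0, 1, length.out = n_bins + 1L),
                 names = FALSE, type = 7)
  br <- unique(br)
  bin <- cut(lm, breaks = br, include.lowest = TRUE)
  centers <- tapply(m, bin, median)
  meds <- tapply(v, bin, median)
  keep <- !is.na(centers) & !is.na(meds)
  grid <- data.frame(mu = as.numeric(centers[keep]),
                     value = as.numeric(meds[keep]))
  grid <- grid[order(grid$mu), , drop = FALSE]
  f <- if (nrow(grid) == 1L) {
    function(x) rep(grid$value, length(x))
  } else {
    approxfun(grid$mu, grid$value, rule = 2)  # constant extrapolation
  }
  attr(f, "grid") <- grid
  attr(f, "what") <- what
  f
}

#' Running-median mean-dispersion trend
#'
#' Bins features into `n_bins` equal-occupancy bins of log mean, takes the
#' median dispersion per bin, and interpolates linearly between the bin
#' centers (median mean per bin), with constant extrapolation beyond the
#' outermost centers.
#'
#' @param means per-feature means (> 0 used).
#' @param dispersions per-feature MoM dispersions.
#' @param n_bins number of bins (default 20; reduced with a warning when
#'   features are scarce).
#' @return a function mean -> trend dispersion, with the bin grid in
#'   attribute `"grid"`.
#' @export
dispersionTrend <- function(means, dispersions, n_bins = 20L) {
  runningMedianTrend(means, dispersions, n_bins, what = "dispersion")
}

#' Dispersion / BCV characterization of a dataset
#'
#' Size-factor-normalizes the counts (median-of-ratios), takes per-feature
#' moments, the MoM dispersion, `bcv = sqrt(phi)`, the per-feature mean of
#' log2-CPM (the conventional x-axis of BCV plots) and the running-median
#' mean-dispersion trend.
#'
#' With `byClass = FALSE` (default) the moments are marginal, ignoring any
#' sample grouping — the convention of mean-dispersion and mean-variance
#' diagnostic plots.  With `byClass = TRUE` the dispersion of each feature
#' is the degrees-of-freedom-weighted average of the per-class MoM
#' dispersions, so designed between-class shifts do not masquerade as
#' biological variability; this is the estimate the Wald test consumes.
#'
#' @param object a [CountDataSet-class] with >= 2 samples.
#' @param n_bins trend bins (default 20).
#' @param prior log2-CPM prior count (default 0.5).
#' @param byClass estimate dispersion within classes (default `FALSE`).
#' @return a [DispersionEstimates-class].
#' @examples
#' cds <- makeFixture("null_nb", seed = 1, nFeatures = 200, nPerClass = 10)
#' de <- estimateDispersionsMoM(cds)
#' de
#' @export
estimateDispersionsMoM <- function(object, n_bins = 20L, prior = 0.5,
                                   byClass = FALSE) {
  stopifnot(is(object, "CountDataSet"))
  sf <- sizeFactorsMoR(object)
  mom <- geneMoments(object, sizeFactors = sf)
  if (byClass) {
    cls <- requireTwoClasses(object, minPerClass = 2L)
    phiSum <- 0; dfSum <- 0
    for (k in 1:2) {
      sel <- cls == k
      momK <- geneMoments(counts(object)[, sel, drop = FALSE],
                          sizeFactors = sf[sel])
      df <- sum(sel) - 1L
      phiSum <- phiSum + df * momDispersion(momK$mean, momK$variance)
      dfSum <- dfSum + df
    }
    phi <- phiSum / dfSum
  } else {
    phi <- momDispersion(mom$mean, mom$variance)
  }
  trend <- dispersionTrend(mom$mean, phi, n_bins = n_bins)
  tab <- S4Vectors::DataFrame(
    mean_log2cpm = rowMeans(cpmCounts(object, log2 = TRUE, prior = prior)),
    mu = mom$mean,
    phi = phi,
    bcv = sqrt(phi),
    trend_value = trend(mom$mean),
    row.names = rownames(object))
  new("DispersionEstimates", table = tab, trend = trend,
      trendGrid = data.frame(mu = attr(trend, "grid")$mu,
                             phi = attr(trend, "grid")$value))
}

setMethod("show", "DispersionEstimates", function(object) {
  cat("DispersionEstimates: ", nrow(object@table), " features\n",
      "  median phi ", format(median(object@table$phi), digits = 4),
      ", median BCV ", format(median(object@table$bcv), digits = 4), "\n",
      "  trend grid: ", nrow(object@trendGrid), " bins over mu in [",
      format(min(object@trendGrid$mu), digits = 3), ", ",
      format(max(object@trendGrid$mu), digits = 3), "]\n", sep = "")
})

#' Accessors for DispersionEstimates
#'
#' @param object a [DispersionEstimates-class].
#' @return `dispersionTable`: the per-feature DataFrame; `trendFunction`:
#'   the fitted mean -> dispersion function.
#' @export
dispersionTable <- function(object) {
  stopifnot(is(object, "DispersionEstimates")); object@table
}

#' @rdname dispersionTable
#' @export
trendFunction <- function(object) {
  stopifnot(is(object, "DispersionEstimates")); object@trend
}

# Shared log-mean grid between two trend objects: quantiles of the union of
# the two bin-center ranges, restricted to the overlap when there is one.
sharedMeanGrid <- function(gridA, gridB, n = 50L) {
  lo <- max(min(gridA$mu), min(gridB$mu))
  hi <- min(max(gridA$mu), max(gridB$mu))
  if (!(hi > lo)) { lo <- min(gridA$mu, gridB$mu); hi <- max(gridA$mu, gridB$mu) }
  exp(seq(log(lo), log(hi), length.out = n))
}

#' Distance between two mean-dispersion trends
#'
#' `median(|log((trend_a(m) + delta) / (trend_b(m) + delta))|)` over a
#' shared log-spaced mean grid; 0 when a dataset is compared with itself.
#'
#' @param a,b [DispersionEstimates-class] objects.
#' @param delta stabilizer for near-zero dispersions (default `1e-3`).
#' @param n grid size (default 50).
#' @return non-negative scalar.
#' @export
dispersionDistance <- function(a, b, delta = 1e-3, n = 50L) {
  stopifnot(is(a, "DispersionEstimates"), is(b, "DispersionEstimates"))
  grid <- sharedMeanGrid(attr(a@trend, "grid"), attr(b@trend, "grid"), n)
  median(abs(log((a@trend(grid) + delta) / (b@trend(grid) + delta))))
}

#' Mean-variance trend and distance
#'
#' The mean-variance relationship of a dataset, summarized the same way as
#' the dispersion trend: equal-occupancy bins of log mean, median variance
#' per bin, linear interpolation.  `meanVarianceDistance` is the median
#' absolute log-ratio of two such trends on a shared grid.
#'
#' @param object a [CountDataSet-class].
#' @param n_bins trend bins (default 20).
#' @return `meanVarianceTrend`: a function mean -> variance with the bin
#'   grid in attribute `"grid"`.
#' @export
meanVarianceTrend <- function(object, n_bins = 20L) {
  mom <- geneMoments(object)
  runningMedianTrend(mom$mean, mom$variance, n_bins, what = "variance")
}

#' @rdname meanVarianceTrend
#' @param a,b trend functions from `meanVarianceTrend`.
#' @param delta stabilizer (default `1e-3`).
#' @param n grid size (default 50).
#' @export
meanVarianceDistance <- function(a, b, delta = 1e-3, n = 50L) {
  grid <- sharedMeanGrid(attr(a, "grid"), attr(b, "grid"), n)
  median(abs(log((a(grid) + delta) / (b(grid) + delta))))
}

#' Export the per-feature dispersion table as TSV
#'
#' Columns: `feature_id`, `mean_log2cpm`, `mom_dispersion`, `bcv`,
#' `trend_value`.
#'
#' @param object a [DispersionEstimates-class].
#' @param path output TSV.
#' @export
writeDispersionTable <- function(object, path) {
  tab <- dispersionTable(object)
  df <- data.frame(feature_id = rownames(tab),
                   mean_log2cpm = tab$mean_log2cpm,
                   mom_dispersion = tab$phi,
                   bcv = tab$bcv,
                   trend_value = tab$trend_value)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
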