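#' Remove features with an all-sample median of zero
#'
#' Retains exactly the features whose per-feature median count across all
#' samples is greater than zero, preserving order.  This is the standard
#' low-expression filter applied to an input dataset before benchmarking;
#' it is idempotent.
#'
#' @param object a [CountDataSet-class].
#' @return the filtered dataset (a warning is emitted if nothing survives).
#' @export
filterZeroMedian <- function(object) {
  stopifnot(is(object, "CountDataSet"))
  if (nrow(object) == 0L) stop("empty count matrix")
  med <- apply(counts(object), 1L, median)
  keep <- med > 0
  if (!any(keep)) warning("all features have zero median; result is empty")
  object[keep, ]
}

#' Subset to a balanced two-class design
#'
#' Samples without replacement exactly `nPerClass` samples from each class,
#' reproducibly given a seed — the "50 patients and 50 controls" style
#' preparation of an input dataset.
#'
#' @param object a [CountDataSet-class] with class labels.
#' @param nPerClass samples to keep per class.
#' @param seed seed for the (seeded sub-stream) sampling.
#' @return the subset dataset, class-1 samples first.
#' @export
subsetBalanced <- function(object, nPerClass, seed = 1) {
  cls <- requireTwoClasses(object)
  nPerClass <- as.integer(nPerClass)
  for (k in 1:2) {
    have <- sum(cls == k)
    if (have < nPerClass)
      stop(sprintf("class %d has %d samples, need %d", k, have, nPerClass))
  }
  set.seed(stageSeed(seed, "subset"))
  pick1 <- sort(sample(which(cls == 1L), nPerClass))
  pick2 <- sort(sample(which(cls == 2L), nPerClass))
  object[, c(pick1, pick2)]
}

#' Truncate extreme counts to a ceiling
#'
#' Replaces every entry strictly above `ceiling` (default `1e7`) by
#' `ceiling`, the outlier-control rule applied to real input data before
#' parameter estimation.  The number of truncated entries is recorded in
#' `metadata(x)$n_truncated` and reported via a message.
#'
#' @param object a [CountDataSet-class].
#' @param ceiling positive integer ceiling (default `1e7`).
#' @return the truncated dataset.
#' @export
truncateOutliers <- function(object, ceiling = 1e7) {
  stopifnot(is(object, "CountDataSet"))
  if (ceiling <= 0) stop("ceiling must be positive")
  cnt <- counts(object)
  over <- cnt > ceiling
  n <- sum(over)
  if (n > 0L) {
    cnt[over] <- as.integer(ceiling)
    SummarizedExperiment::assay(object, "counts") <- cnt
  }
  S4Vectors::metadata(object)$n_truncated <- n
  message(n, " entries truncated to ", format(ceiling, scientific = FALSE))
  object
}
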