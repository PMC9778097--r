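#' Principal-component embedding of samples
#'
#' PCA of the samples-by-features matrix of log2-CPM values (prior 0.5, all
#' features), centered per feature, unscaled.  Signs are fixed
#' deterministically: each component is flipped so that its
#' largest-magnitude feature loading is positive.
#'
#' @param object a [CountDataSet-class] with >= 3 samples and >= 2
#'   features.
#' @param n_components number of components to return (default 2).
#' @param topFeatures optionally restrict to the `topFeatures` most
#'   variable features before the PCA (default `NULL` = all).
#' @return list with `scores` (samples x components, columns `PC1`, ...;
#'   zero column means) and `variance_explained` (fractions, non-increasing).
#' @export
pcaEmbed <- function(object, n_components = 2L, topFeatures = NULL) {
  stopifnot(is(object, "CountDataSet"))
  if (ncol(object) < 3L) stop("need at least 3 samples")
  if (nrow(object) < 2L) stop("need at least 2 features")
  x <- t(cpmCounts(object, log2 = TRUE, prior = 0.5))
  if (!is.null(topFeatures)) {
    v <- apply(x, 2L, var)
    x <- x[, order(v, decreasing = TRUE)[seq_len(min(topFeatures, ncol(x)))],
           drop = FALSE]
  }
  if (all(apply(x, 2L, var) == 0)) stop("constant matrix: PCA undefined")
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    load <- pc$rotation[, j]
    if (load[which.max(abs(load))] < 0) scores[, j] <- -scores[, j]
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = scores, variance_explained = ve[seq_len(k)])
}

#' Class separability as a mean silhouette width
#'
#' Mean silhouette coefficient of the samples on their (PC1, PC2)
#' coordinates with Euclidean distance, using the two class labels as the
#' clustering.  Values near 1 indicate clearly separated classes, values
#' near 0 thoroughly mixed ones.
#'
#' @param scores samples x 2 score matrix (e.g. `pcaEmbed(x)$scores`).
#' @param labels two-class labels, one per sample, each class >= 2 samples.
#' @return mean silhouette width in `[-1, 1]`.
#' @export
separabilityScore <- function(scores, labels) {
  labels <- as.integer(factor(labels))
  if (length(unique(labels)) != 2L)
    stop("exactly two classes are required")
  if (min(table(labels)) < 2L)
    stop("each class needs at least 2 samples (singleton class)")
  stopifnot(nrow(scores) == length(labels))
  sil <- cluster::silhouette(labels, stats::dist(scores[, 1:2, drop = FALSE]))
  mean(sil[, "sil_width"])
}

#' One-call separability assessment
#'
#' @param object a [CountDataSet-class] with class labels.
#' @param ... passed to [pcaEmbed()].
#' @return list with `scores`, `variance_explained` and `silhouette`.
#' @examples
#' cds <- makeFixture("two_blob", seed = 1)
#' assessSeparability(cds)$silhouette
#' @export
assessSeparability <- function(object, ...) {
  cls <- requireTwoClasses(object, minPerClass = 2L)
  emb <- pcaEmbed(object, ...)
  c(emb, list(silhouette = separabilityScore(emb$scores, cls)))
}
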