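#' Simulation parameters for the two-class ground-truth count generator
#'
#' `SimParams` holds every knob of the latent multivariate-Gaussian /
#' Poisson-read simulator: dimensions, class sizes, differential-expression
#' design, the latent noise level `sigma`, the compound-symmetry correlation
#' blocks, and the depth-calibration target.
#'
#' @slot nFeatures number of features (genes) simulated.
#' @slot nPerClass integer vector of length 2, samples in class 1 and class 2.
#' @slot nSubgroupsClass1 number of subgroups within class 1 (heterogeneous
#'   markers shift only in a subset of these).
#' @slot deFraction fraction of features flagged as global DE markers; used
#'   when `nGlobalMarkers` is `NA`.
#' @slot nGlobalMarkers explicit number of global DE markers (`NA` = derive
#'   from `deFraction` as `round(deFraction * nFeatures)`).
#' @slot nHeteroMarkers number of heterogeneous markers (shift only in
#'   `ceiling(nSubgroupsClass1 / 2)` randomly chosen class-1 subgroups).
#' @slot baselineLogMean latent natural-log mean concentration of every
#'   feature before depth calibration.
#' @slot lfcDE designed log2 fold change of DE features (class 2 over class 1);
#'   applied as an additive shift of `lfcDE * ln(2)` on the latent log scale.
#' @slot sigma latent log-scale standard deviation (the paper-style presets
#'   use 0.4 for the separable and 0.7 for the mixed scenario).
#' @slot blockSize number of features per correlation block.
#' @slot blockRho common within-block latent correlation; must exceed
#'   `-1/(blockSize - 1)` for positive definiteness.
#' @slot nBlocks number of disjoint correlation blocks.
#' @slot targetMeanCount target for the overall mean count per matrix entry
#'   after empirical depth calibration.
#' @slot depthJitter length-2 numeric `(low, high)`; per-sample depth factors
#'   drawn uniformly from this interval. `(1, 1)` disables depth variation.
#' @slot seed default root seed used when none is passed to
#'   [simulateDataset()].
#'
#' @seealso [simParams()], [simParamsPreset()], [simulateDataset()]
#' @export
setClass("SimParams", representation(
  nFeatures = "integer",
  nPerClass = "integer",
  nSubgroupsClass1 = "integer",
  deFraction = "numeric",
  nGlobalMarkers = "integer",
  nHeteroMarkers = "integer",
  baselineLogMean = "numeric",
  lfcDE = "numeric",
  sigma = "numeric",
  blockSize = "integer",
  blockRho = "numeric",
  nBlocks = "integer",
  targetMeanCount = "numeric",
  depthJitter = "numeric",
  seed = "integer"
))

setValidity("SimParams", function(object) {
  msg <- character()
  chk1 <- function(x, nm) {
    if (length(x) != 1L || is.na(x)) msg <<- c(msg, paste0(nm, " must be a single non-missing value"))
  }
  chk1(object@nFeatures, "nFeatures"); chk1(object@sigma, "sigma")
  chk1(object@deFraction, "deFraction"); chk1(object@targetMeanCount, "targetMeanCount")
  if (length(msg)) return(msg)
  if (object@nFeatures < 1L) msg <- c(msg, "nFeatures must be positive")
  if (length(object@nPerClass) != 2L || any(object@nPerClass < 1L))
    msg <- c(msg, "nPerClass must be two positive integers")
  if (object@nSubgroupsClass1 < 1L) msg <- c(msg, "nSubgroupsClass1 must be >= 1")
  if (object@deFraction < 0 || object@deFraction > 1)
    msg <- c(msg, "deFraction must lie in [0, 1]")
  if (!is.na(object@nGlobalMarkers) &&
      (object@nGlobalMarkers < 0L || object@nGlobalMarkers > object@nFeatures))
    msg <- c(msg, "nGlobalMarkers must lie in [0, nFeatures]")
  if (object@nHeteroMarkers < 0L) msg <- c(msg, "nHeteroMarkers must be >= 0")
  if (object@sigma < 0) msg <- c(msg, "sigma must be non-negative")
  if (object@blockSize < 2L) msg <- c(msg, "blockSize must be >= 2")
  if (object@nBlocks < 0L) msg <- c(msg, "nBlocks must be >= 0")
  if (object@blockRho <= -1 / (object@blockSize - 1L) || object@blockRho >= 1)
    msg <- c(msg, sprintf(
      "blockRho = %g violates positive definiteness for blockSize = %d (must lie in (%.4f, 1))",
      object@blockRho, object@blockSize, -1 / (object@blockSize - 1L)))
  if (object@nBlocks * object@blockSize > object@nFeatures)
    msg <- c(msg, "nBlocks * blockSize exceeds nFeatures")
  if (object@targetMeanCount <= 0) msg <- c(msg, "targetMeanCount must be positive")
  if (length(object@depthJitter) != 2L || any(object@depthJitter <= 0) ||
      object@depthJitter[1L] > object@depthJitter[2L])
    msg <- c(msg, "depthJitter must be positive (low, high) with low <= high")
  nDE <- if (is.na(object@nGlobalMarkers)) {
    round(object@deFraction * object@nFeatures)
  } else object@nGlobalMarkers
  if (nDE + object@nHeteroMarkers + object@nBlocks * object@blockSize > object@nFeatures)
    msg <- c(msg, "markers plus block features exceed nFeatures (blocks are drawn from non-DE features)")
  if (length(msg)) msg else TRUE
})

#' Two-class count dataset with optional simulation ground truth
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] subclass whose
#' `"counts"` assay is a non-negative integer-valued matrix with unique
#' feature and sample identifiers.  Sample class labels (1 or 2) live in
#' `colData(x)$class`, an optional class-1 subgroup in `colData(x)$subgroup`.
#' For simulated data, the per-feature ground truth (`de_flag`, `true_lfc`,
#' `block_id`) is carried in `rowData`.
#'
#' @seealso [CountDataSet()], [classLabels()], [deFlags()], [trueLfc()],
#'   [blockIds()]
#' @export
setClass("CountDataSet", contains = "SummarizedExperiment")

setValidity("CountDataSet", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is required")
  cnt <- SummarizedExperiment::assay(object, "counts")
  if (is.null(rownames(object)) || is.null(colnames(object)))
    msg <- c(msg, "feature and sample identifiers are required (dimnames)")
  else {
    if (anyDuplicated(rownames(object))) msg <- c(msg, "duplicate feature identifiers")
    if (anyDuplicated(colnames(object))) msg <- c(msg, "duplicate sample identifiers")
  }
  if (!is.numeric(cnt)) msg <- c(msg, "counts must be numeric")
  else {
    if (any(!is.finite(cnt))) msg <- c(msg, "counts must be finite")
    else {
      if (any(cnt < 0)) msg <- c(msg, "counts must be non-negative")
      if (!all(isWholeNumber(cnt))) msg <- c(msg, "counts must be integer-valued")
    }
  }
  cls <- SummarizedExperiment::colData(object)$class
  if (!is.null(cls) && !all(cls %in% c(1L, 2L)))
    msg <- c(msg, "colData$class must contain only 1 and 2")
  if (length(msg)) msg else TRUE
})

#' Per-feature dispersion estimates with a fitted mean-dispersion trend
#'
#' Container for the method-of-moments negative-binomial dispersion
#' characterization of a count dataset: per-feature normalized mean, MoM
#' dispersion `phi` (`Var = mu + phi * mu^2`), biological coefficient of
#' variation `bcv = sqrt(phi)`, the mean of log2-CPM, and a running-median
#' mean-dispersion trend evaluated on an interpolation grid.
#'
#' @slot table a [S4Vectors::DataFrame] with columns `mean_log2cpm`, `mu`,
#'   `phi`, `bcv`, `trend_value`, one row per feature.
#' @slot trend a function mapping normalized mean to trend dispersion
#'   (linear interpolation between equal-occupancy bin centers, constant
#'   beyond).
#' @slot trendGrid data.frame of bin centers (`mu`) and bin median
#'   dispersions (`phi`) the trend interpolates.
#' @seealso [estimateDispersionsMoM()], [dispersionDistance()]
#' @export
setClass("DispersionEstimates", representation(
  table = "DataFrame",
  trend = "function",
  trendGrid = "data.frame"
))

#' Differential-expression results from the negative-binomial Wald test
#'
#' Extends [S4Vectors::DataFrame] with columns `baseMean`, `lfc` (log2),
#' `se`, `wald`, `pvalue` and `qvalue` (Benjamini-Hochberg), one row per
#' feature.  Produced by [nbWaldTest()].
#'
#' @export
setClass("DEResults", contains = "DFrame")

#' Per-dataset benchmarking report entry
#'
#' One input-vs-synthetic comparison across the full metric battery, as
#' produced by [assessPair()]: aggregated Q-Q concordance, dispersion- and
#' mean-variance trend distances, feature-feature correlation distance,
#' DEG counts on both datasets, sign balance, and class-separability
#' silhouettes.  A list of these feeds [compareGenerators()].
#'
#' @slot generator label of the synthetic dataset / generator.
#' @slot qq named numeric vector: mean `slope`, `intercept`,
#'   `max_abs_deviation`, `ks_stat` over compared sample pairs.
#' @slot dispersionDistance median absolute log-ratio of the two
#'   mean-dispersion trends over a shared mean grid.
#' @slot meanVarianceDistance same scalarization for mean-variance trends.
#' @slot correlationDistance two-sample KS distance between Spearman
#'   correlation distributions of 25 sampled non-constant features.
#' @slot degCount,degCountInput BH-significant feature counts at `alpha`.
#' @slot signBalance fraction of significant features with positive lfc in
#'   the synthetic dataset (`NaN` when nothing is significant).
#' @slot silhouetteSynth,silhouetteInput mean silhouette width on (PC1, PC2).
#' @slot settings list of the configuration actually used (transforms,
#'   pairing strategy, thresholds, seed) — the run log.
#' @export
setClass("MetricReport", representation(
  generator = "character",
  qq = "numeric",
  dispersionDistance = "numeric",
  meanVarianceDistance = "numeric",
  correlationDistance = "numeric",
  degCount = "integer",
  degCountInput = "integer",
  signBalance = "numeric",
  silhouetteSynth = "numeric",
  silhouetteInput = "numeric",
  settings = "list"
))
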