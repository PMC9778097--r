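#' Construct simulation parameters
#'
#' Builds a validated [SimParams-class] object.  Defaults reproduce the
#' "separable" preset design: 10,000 features, 50 samples per class, 5%
#' global DE markers at log2 fold change 1, one 5-feature correlation block
#' at latent correlation 0.4, latent noise `sigma = 0.4`, and a calibrated
#' overall mean of 300 reads per feature.
#'
#' @param nFeatures number of features (default 10000).
#' @param nPerClass samples per class, length-2 (default `c(50, 50)`).
#' @param nSubgroupsClass1 subgroups within class 1 (default 1).
#' @param deFraction fraction of global DE markers (default 0.05); ignored
#'   when `nGlobalMarkers` is given.
#' @param nGlobalMarkers explicit number of global DE markers, or `NA`.
#' @param nHeteroMarkers heterogeneous markers, shifting only in
#'   `ceiling(nSubgroupsClass1/2)` randomly chosen class-1 subgroups
#'   (default 0).
#' @param baselineLogMean latent natural-log baseline concentration
#'   (default 0; the absolute level is irrelevant after depth calibration).
#' @param lfcDE designed log2 fold change for DE features (default 1).
#' @param sigma latent log-scale standard deviation (default 0.4).
#' @param blockSize features per correlation block (default 5).
#' @param blockRho within-block latent correlation (default 0.4).
#' @param nBlocks number of disjoint blocks (default 1).
#' @param targetMeanCount depth-calibration target (default 300).
#' @param depthJitter per-sample uniform depth-factor range (default
#'   `c(1, 1)`, i.e. off).
#' @param seed default root seed (default 1).
#' @return a `SimParams` object.
#' @examples
#' p <- simParams(nFeatures = 500, nPerClass = c(10, 10))
#' nDEFeatures(p)
#' @export
simParams <- function(nFeatures = 10000, nPerClass = c(50, 50),
                      nSubgroupsClass1 = 1, deFraction = 0.05,
                      nGlobalMarkers = NA, nHeteroMarkers = 0,
                      baselineLogMean = 0, lfcDE = 1, sigma = 0.4,
                      blockSize = 5, blockRho = 0.4, nBlocks = 1,
                      targetMeanCount = 300, depthJitter = c(1, 1),
                      seed = 1) {
  new("SimParams",
      nFeatures = as.integer(nFeatures),
      nPerClass = as.integer(nPerClass),
      nSubgroupsClass1 = as.integer(nSubgroupsClass1),
      deFraction = as.numeric(deFraction),
      nGlobalMarkers = as.integer(nGlobalMarkers),
      nHeteroMarkers = as.integer(nHeteroMarkers),
      baselineLogMean = as.numeric(baselineLogMean),
      lfcDE = as.numeric(lfcDE),
      sigma = as.numeric(sigma),
      blockSize = as.integer(blockSize),
      blockRho = as.numeric(blockRho),
      nBlocks = as.integer(nBlocks),
      targetMeanCount = as.numeric(targetMeanCount),
      depthJitter = as.numeric(depthJitter),
      seed = as.integer(seed))
}

#' Named simulation presets
#'
#' `"ngssppg1"` is the separable two-class scenario (latent sigma 0.4) and
#' `"ngssppg2"` the mixed, harder one (sigma 0.7); both are 10,000 features
#' by 100 samples (50/50), 5% DE, one 5-feature block at correlation 0.4,
#' mean count calibrated to 300.  The `"-small"` variants keep every
#' statistical setting and shrink the dimensions to 500 features by 20
#' samples for examples and tests.
#'
#' @param preset one of `"ngssppg1"`, `"ngssppg2"`, `"ngssppg1-small"`,
#'   `"ngssppg2-small"`.
#' @param ... overrides forwarded to [simParams()] fields.
#' @return a [SimParams-class] object.
#' @examples
#' simParamsPreset("ngssppg2-small")
#' @export
simParamsPreset <- function(preset, ...) {
  base <- switch(preset,
    "ngssppg1" = list(sigma = 0.4),
    "ngssppg2" = list(sigma = 0.7),
    "ngssppg1-small" = list(sigma = 0.4, nFeatures = 500, nPerClass = c(10, 10)),
    "ngssppg2-small" = list(sigma = 0.7, nFeatures = 500, nPerClass = c(10, 10)),
    stop("unknown preset: '", preset, "' (expected ngssppg1, ngssppg2, ",
         "ngssppg1-small or ngssppg2-small)")
  )
  do.call(simParams, modifyList(base, list(...)))
}

#' Number of global DE markers implied by a parameter set
#'
#' `round(deFraction * nFeatures)` when `nGlobalMarkers` is unset (so the
#' default design gives 500 of 10,000, and 5% of 34,616 features gives
#' 1731), otherwise `nGlobalMarkers` itself.
#'
#' @param params a [SimParams-class] object.
#' @return integer count of DE-flagged features.
#' @examples
#' nDEFeatures(simParams(nFeatures = 34616))
#' @export
nDEFeatures <- function(params) {
  stopifnot(is(params, "SimParams"))
  if (is.na(params@nGlobalMarkers)) {
    as.integer(round(params@deFraction * params@nFeatures))
  } else {
    params@nGlobalMarkers
  }
}

setMethod("show", "SimParams", function(object) {
  nde <- nDEFeatures(object)
  cat("SimParams\n",
      sprintf("  %d features x %d+%d samples (class 1 + class 2)\n",
              object@nFeatures, object@nPerClass[1L], object@nPerClass[2L]),
      sprintf("  DE: %d global markers (lfc %.2f), %d heterogeneous\n",
              nde, object@lfcDE, object@nHeteroMarkers),
      sprintf("  latent: sigma %.2f, %d block(s) of %d @ rho %.2f\n",
              object@sigma, object@nBlocks, object@blockSize, object@blockRho),
      sprintf("  depth: target mean %.1f, jitter [%.2f, %.2f]\n",
              object@targetMeanCount, object@depthJitter[1L], object@depthJitter[2L]),
      sep = "")
})
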