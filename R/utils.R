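#' @import methods
#' @importFrom stats approxfun cor ks.test median p.adjust pnorm prcomp
#'   quantile rnorm rpois runif var rnbinom
#' @importFrom utils head modifyList
#' @importClassesFrom S4Vectors DataFrame DFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment assay assayNames colData rowData
NULL

# Deterministic per-stage child seeds from one root seed, so that each
# randomized stage (latent draw, depth jitter, Poisson sampling, feature
# subsampling, ...) is independently reproducible.  Kept strictly below
# 2^31 - 1 (R integers are 32-bit).
stageSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  offsets <- c(
    latent = 11L, pilot = 23L, jitter = 37L, poisson = 41L,
    markers = 53L, blocks = 59L, subgroups = 61L, subset = 67L,
    features = 71L, offpairs = 73L, qqpairs = 79L
  )
  if (!stage %in% names(offsets)) {
    stop("unknown RNG stage: ", stage)
  }
  as.integer((abs(seed) * 7919 + offsets[[stage]]) %% 2147483647)
}

# Integral within floating-point tolerance (counts read from text files may
# arrive as doubles).
isWholeNumber <- function(x, tol = 1e-8) {
  is.finite(x) & abs(x - round(x)) < tol
}

`%||%` <- function(a, b) if (is.null(a)) b else a
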