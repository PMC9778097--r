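#' Ground-truth design: marker and block assignment
#'
#' Draws the per-feature design underlying a simulation: which features are
#' global DE markers, which belong to which correlation block (blocks are
#' disjoint and drawn from the non-DE features, so designed correlation is
#' never confounded with designed mean shifts), which are heterogeneous
#' markers, the per-sample class labels and class-1 subgroup labels, and
#' which subgroups the heterogeneous shift applies to
#' (`ceiling(nSubgroupsClass1 / 2)` of them, chosen at random).
#'
#' @param params a [SimParams-class].
#' @param seed root seed; stage-specific child seeds are derived from it.
#' @return list with `deIdx`, `heteroIdx`, `blocks` (list of integer index
#'   vectors), `classLabels`, `subgroup`, `heteroSubgroups`.
#' @export
designGroundTruth <- function(params, seed = params@seed) {
  stopifnot(is(params, "SimParams"))
  G <- params@nFeatures
  nDE <- nDEFeatures(params)
  set.seed(stageSeed(seed, "markers"))
  deIdx <- sort(sample.int(G, nDE))
  pool <- setdiff(seq_len(G), deIdx)
  set.seed(stageSeed(seed, "blocks"))
  blocks <- list()
  if (params@nBlocks > 0L) {
    picked <- sample(pool, params@nBlocks * params@blockSize)
    blocks <- split(sort(picked),
                    rep(seq_len(params@nBlocks), each = params@blockSize))
    blocks <- lapply(blocks, as.integer)
    pool <- setdiff(pool, picked)
  }
  heteroIdx <- integer()
  if (params@nHeteroMarkers > 0L) {
    heteroIdx <- sort(sample(pool, params@nHeteroMarkers))
  }
  n1 <- params@nPerClass[1L]; n2 <- params@nPerClass[2L]
  classLabels <- rep(c(1L, 2L), c(n1, n2))
  subgroup <- rep(NA_integer_, n1 + n2)
  subgroup[classLabels == 1L] <-
    rep_len(seq_len(params@nSubgroupsClass1), n1)
  set.seed(stageSeed(seed, "subgroups"))
  heteroSubgroups <- sort(sample.int(
    params@nSubgroupsClass1, ceiling(params@nSubgroupsClass1 / 2)))
  list(deIdx = deIdx, heteroIdx = heteroIdx, blocks = blocks,
       classLabels = classLabels, subgroup = subgroup,
       heteroSubgroups = heteroSubgroups)
}

#' Block-structured feature correlation
#'
#' The designed latent correlation matrix: unit diagonal, compound-symmetry
#' blocks (all off-diagonals within a designated block equal `blockRho`),
#' zero elsewhere.  Returned as a compact block description (the full matrix
#' for 10,000 features would be 800 MB); `as.matrix()` materializes it for
#' small dimensions.
#'
#' @param params a [SimParams-class]; `blockRho` must exceed
#'   `-1/(blockSize-1)` so each block (eigenvalues `1+(k-1)rho` and `1-rho`)
#'   is positive definite.
#' @param seed root seed used to place blocks among features.
#' @param blocks optionally, pre-drawn block index vectors (as from
#'   [designGroundTruth()]), overriding the seeded placement.
#' @return an object of class `"blockCorrelation"` with elements
#'   `nFeatures`, `rho` and `blocks`.
#' @examples
#' R <- buildCovariance(simParams(nFeatures = 10, nPerClass = c(2, 2),
#'                                deFraction = 0))
#' as.matrix(R)[1:6, 1:6]
#' @export
buildCovariance <- function(params, seed = params@seed, blocks = NULL) {
  stopifnot(is(params, "SimParams"))
  validObject(params)
  if (is.null(blocks)) blocks <- designGroundTruth(params, seed)$blocks
  structure(
    list(nFeatures = params@nFeatures, rho = params@blockRho,
         blocks = blocks),
    class = "blockCorrelation")
}

#' @export
as.matrix.blockCorrelation <- function(x, ...) {
  R <- diag(x$nFeatures)
  for (idx in x$blocks) {
    R[idx, idx] <- x$rho
    diag(R)[idx] <- 1
  }
  R
}

#' @export
print.blockCorrelation <- function(x, ...) {
  cat("blockCorrelation: ", x$nFeatures, " features, ",
      length(x$blocks), " block(s) @ rho ", x$rho, "\n", sep = "")
  invisible(x)
}

# Lower-triangular factor of a k x k compound-symmetry correlation matrix.
compoundSymmetryFactor <- function(k, rho) {
  R <- matrix(rho, k, k); diag(R) <- 1
  t(chol(R))
}

#' Latent log-concentration draw
#'
#' Each sample (column) is one draw from a multivariate normal with mean
#' vector determined by its class (DE features in class 2 are shifted by
#' `lfcDE * ln(2)`; heterogeneous markers are shifted only in the designated
#' class-1 subgroups) and covariance `sigma^2 * R`, with `R` the
#' block-structured correlation of [buildCovariance()].  Exponentiated, the
#' draw is the vector of per-feature mRNA concentrations feeding the Poisson
#' read model.
#'
#' @param params a [SimParams-class].
#' @param seed root seed (reproducible: identical seed, identical matrix).
#' @param truth optional design from [designGroundTruth()]; drawn from
#'   `seed` when omitted.
#' @return `nFeatures x nSamples` numeric matrix of latent natural-log
#'   concentrations, with the design attached as attribute `"truth"`.
#' @export
simulateLogConcentrations <- function(params, seed = params@seed,
                                      truth = NULL) {
  stopifnot(is(params, "SimParams"))
  validObject(params)
  if (is.null(truth)) truth <- designGroundTruth(params, seed)
  G <- params@nFeatures
  n <- sum(params@nPerClass)
  mu <- matrix(params@baselineLogMean, G, n)
  shift <- params@lfcDE * log(2)
  mu[truth$deIdx, truth$classLabels == 2L] <-
    mu[truth$deIdx, truth$classLabels == 2L] + shift
  if (length(truth$heteroIdx)) {
    hcols <- which(truth$classLabels == 1L &
                   truth$subgroup %in% truth$heteroSubgroups)
    mu[truth$heteroIdx, hcols] <- mu[truth$heteroIdx, hcols] + shift
  }
  set.seed(stageSeed(seed, "latent"))
  Z <- matrix(rnorm(G * n), G, n)
  for (idx in truth$blocks) {
    L <- compoundSymmetryFactor(length(idx), params@blockRho)
    Z[idx, ] <- L %*% Z[idx, ]
  }
  latent <- mu + params@sigma * Z
  attr(latent, "truth") <- truth
  latent
}

# Per-sample depth factors, shared between calibration and final sampling.
depthFactors <- function(params, seed) {
  n <- sum(params@nPerClass)
  if (params@depthJitter[1L] == params@depthJitter[2L])
    return(rep(params@depthJitter[1L], n))
  set.seed(stageSeed(seed, "jitter"))
  runif(n, params@depthJitter[1L], params@depthJitter[2L])
}

#' Empirical depth calibration
#'
#' Finds the multiplicative rate scale that brings the overall mean count of
#' a pilot simulation (same dimensions as the target dataset) to within 1%
#' of `targetMeanCount`, by fixed-point iteration
#' `a <- a * target / empirical_mean` on Poisson draws with a fixed pilot
#' seed, at most `maxIter` rounds.
#'
#' @param params a [SimParams-class].
#' @param seed root seed for the pilot.
#' @param latent optional pre-computed latent matrix to calibrate against
#'   (the pipeline passes its own draw); drawn from `seed` when omitted.
#' @param tol relative tolerance on the pilot mean (default 0.01).
#' @param maxIter iteration cap (default 20); non-convergence is an error
#'   reporting the last pilot mean.
#' @return the scale, a positive scalar.
#' @export
calibrateDepth <- function(params, seed = params@seed, latent = NULL,
                           tol = 0.01, maxIter = 20L) {
  stopifnot(is(params, "SimParams"))
  if (params@targetMeanCount <= 0) stop("targetMeanCount must be positive")
  if (is.null(latent)) latent <- simulateLogConcentrations(params, seed)
  d <- depthFactors(params, seed)
  rates <- exp(latent) * rep(d, each = nrow(latent))
  a <- 1
  emp <- NA_real_
  for (iter in seq_len(maxIter)) {
    set.seed(stageSeed(seed, "pilot"))
    emp <- mean(rpois(length(rates), a * rates))
    if (abs(emp - params@targetMeanCount) <= tol * params@targetMeanCount)
      return(a)
    if (emp == 0) emp <- .Machine$double.eps  # all-zero pilot: push scale up
    a <- a * params@targetMeanCount / emp
  }
  stop(sprintf(
    "depth calibration did not converge in %d iterations (last pilot mean %.4f, target %.1f)",
    maxIter, emp, params@targetMeanCount))
}

#' Poisson read sampling
#'
#' Draws `count(g, s) ~ Poisson(scale * d_s * exp(latent(g, s)))` with
#' per-sample depth factors `d_s` uniform on `depthJitter`.
#'
#' @param latent latent log-concentration matrix from
#'   [simulateLogConcentrations()].
#' @param scale positive rate scale, usually from [calibrateDepth()].
#' @param params a [SimParams-class].
#' @param seed root seed; the Poisson stream is its own child stream, so a
#'   fixed seed gives a bitwise-identical matrix.
#' @param rateCeiling guard against overflow: any rate above this (default
#'   `1e12`) is an error.
#' @return integer count matrix with `gene_*` / `sample_*` dimnames.
#' @export
simulateCounts <- function(latent, scale, params, seed = params@seed,
                           rateCeiling = 1e12) {
  stopifnot(is(params, "SimParams"), is.matrix(latent))
  if (scale < 0) stop("scale must be non-negative")
  d <- depthFactors(params, seed)
  if (length(d) != ncol(latent))
    stop("latent has ", ncol(latent), " columns but the design implies ",
         length(d), " samples")
  rates <- scale * exp(latent) * rep(d, each = nrow(latent))
  if (any(rates > rateCeiling))
    stop(sprintf("Poisson rate %.3g exceeds the ceiling %.3g; check scale/latent",
                 max(rates), rateCeiling))
  set.seed(stageSeed(seed, "poisson"))
  cnt <- matrix(rpois(length(rates), rates), nrow(latent), ncol(latent))
  storage.mode(cnt) <- "integer"
  dimnames(cnt) <- list(paste0("gene_", seq_len(nrow(cnt))),
                        paste0("sample_", seq_len(ncol(cnt))))
  cnt
}

#' Simulate a complete ground-truth dataset
#'
#' End-to-end pipeline: design the ground truth, draw latent
#' log-concentrations under the block covariance, calibrate the sequencing
#' depth to the target mean count, and sample Poisson reads.
#'
#' @param params a [SimParams-class], or a preset name accepted by
#'   [simParamsPreset()].
#' @param seed root seed (defaults to the seed stored in `params`).
#' @param ... preset overrides when `params` is a name.
#' @return a [CountDataSet-class] whose `rowData` carries `de_flag`,
#'   `true_lfc`, `block_id` and `hetero_flag`, whose `colData` carries
#'   `class` and `subgroup`, and whose `metadata` records the parameters,
#'   the calibrated scale and the seed.
#' @examples
#' cds <- simulateDataset("ngssppg1-small", seed = 7)
#' cds
#' sum(deFlags(cds))
#' @export
simulateDataset <- function(params, seed = NULL, ...) {
  if (is.character(params)) params <- simParamsPreset(params, ...)
  stopifnot(is(params, "SimParams"))
  validObject(params)
  if (is.null(seed)) seed <- params@seed
  truth <- designGroundTruth(params, seed)
  latent <- simulateLogConcentrations(params, seed, truth = truth)
  scale <- calibrateDepth(params, seed, latent = latent)
  cnt <- simulateCounts(latent, scale, params, seed)
  G <- params@nFeatures
  de <- logical(G); de[truth$deIdx] <- TRUE
  lfc <- numeric(G); lfc[truth$deIdx] <- params@lfcDE
  blk <- rep(NA_integer_, G)
  for (b in seq_along(truth$blocks)) blk[truth$blocks[[b]]] <- b
  het <- logical(G); het[truth$heteroIdx] <- TRUE
  rd <- S4Vectors::DataFrame(de_flag = de, true_lfc = lfc, block_id = blk,
                             hetero_flag = het, row.names = rownames(cnt))
  CountDataSet(cnt,
               classLabels = truth$classLabels,
               subgroup = truth$subgroup,
               rowData = rd,
               metadata = list(params = params, scale = scale, seed = seed,
                               heteroSubgroups = truth$heteroSubgroups))
}
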