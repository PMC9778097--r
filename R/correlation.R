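#' Select non-constant features for correlation profiling
#'
#' Features with at least two distinct values across samples qualify; if
#' more than `max_n` qualify, a uniform random subset of `max_n` is drawn
#' (seeded), mirroring the 25-feature convention of correlation diagnostic
#' plots.
#'
#' @param object a [CountDataSet-class].
#' @param max_n maximum number of features (default 25).
#' @param seed seed for the subsampling.
#' @return character vector of feature identifiers (empty, with a warning,
#'   when every feature is constant).
#' @export
selectNonconstantFeatures <- function(object, max_n = 25L, seed = 1) {
  stopifnot(is(object, "CountDataSet"))
  cnt <- counts(object)
  nonconst <- which(rowSums(cnt != cnt[, 1L]) > 0L)
  if (length(nonconst) == 0L) {
    warning("no non-constant features")
    return(character())
  }
  if (length(nonconst) > max_n) {
    set.seed(stageSeed(seed, "features"))
    nonconst <- sort(sample(nonconst, max_n))
  }
  rownames(cnt)[nonconst]
}

# Canonical unordered pair index for k features: (1,2), (1,3), ..., (k-1,k).
pairIndex <- function(k) {
  i <- rep(seq_len(k - 1L), times = (k - 1L):1L)
  j <- unlist(lapply(2:k, function(a) seq.int(a, k)))
  cbind(i = i, j = j)
}

#' Pairwise Spearman correlations of selected features
#'
#' Spearman rho (Pearson on average ranks, ties averaged) for every
#' unordered pair of the selected features, in canonical pair order.  By
#' default values are transformed to `log2(count + 1)` and correlations are
#' computed within each class separately then averaged per pair, so that
#' between-class mean shifts (designed DE) cannot masquerade as
#' feature-feature correlation; `perClass = FALSE` pools all samples
#' (the transform is rank-invariant but kept for consistency with the rest
#' of the battery).
#'
#' @param object a [CountDataSet-class] with >= 3 samples.
#' @param features feature identifiers (>= 2), e.g. from
#'   [selectNonconstantFeatures()].
#' @param perClass compute within classes and average (default `TRUE` when
#'   class labels are present).
#' @param log2 transform to `log2(count + 1)` first (default `TRUE`).
#' @return data.frame with columns `feature_i`, `feature_j`, `rho`.
#' @export
spearmanPairs <- function(object, features, perClass = !is.null(classLabels(object)),
                          log2 = TRUE) {
  stopifnot(is(object, "CountDataSet"))
  if (length(features) < 2L) stop("need at least 2 features")
  if (ncol(object) < 3L) stop("need at least 3 samples")
  m <- counts(object)[features, , drop = FALSE]
  if (log2) m <- base::log2(m + 1)
  rhoOf <- function(cols) {
    r <- suppressWarnings(cor(t(m[, cols, drop = FALSE]), method = "spearman"))
    r[pairIndex(length(features))]
  }
  if (perClass) {
    cls <- requireTwoClasses(object, minPerClass = 3L)
    rho <- rowMeans(cbind(rhoOf(which(cls == 1L)), rhoOf(which(cls == 2L))),
                    na.rm = TRUE)
  } else {
    rho <- rhoOf(seq_len(ncol(m)))
  }
  idx <- pairIndex(length(features))
  data.frame(feature_i = features[idx[, "i"]],
             feature_j = features[idx[, "j"]],
             rho = as.numeric(rho))
}

#' Distance between two correlation distributions
#'
#' Two-sample Kolmogorov-Smirnov statistic between the Spearman-rho
#' distributions of two datasets; 0 exactly when the empirical
#' distributions coincide, 1 for disjoint supports.
#'
#' @param rhos_a,rhos_b numeric vectors of correlations (non-empty).
#' @return KS distance in `[0, 1]`.
#' @export
correlationDistance <- function(rhos_a, rhos_b) {
  if (length(rhos_a) == 0L || length(rhos_b) == 0L)
    stop("correlation vectors must be non-empty")
  ksStatistic(rhos_a, rhos_b)
}

#' Recovery of designed correlation blocks
#'
#' For each designed block, the mean pairwise Spearman correlation over
#' within-block pairs, contrasted against a matched seeded random sample of
#' off-block pairs (10x as many as the within-block pairs).
#'
#' @param object a simulated [CountDataSet-class] whose `rowData` carries
#'   `block_id`.
#' @param seed seed for the off-block pair sample.
#' @param perClass,log2 passed to [spearmanPairs()].
#' @return list with `within_block_mean`, `off_block_mean` and `per_block`
#'   (data.frame: `block_id`, `n_pairs`, `mean_rho`).
#' @export
blockRecovery <- function(object, seed = 1, perClass = !is.null(classLabels(object)),
                          log2 = TRUE) {
  blk <- blockIds(object)
  if (is.null(blk) || all(is.na(blk)))
    stop("dataset carries no correlation-block ground truth")
  cnt <- counts(object)
  blockList <- split(which(!is.na(blk)), blk[!is.na(blk)])
  constant <- rowSums(cnt != cnt[, 1L]) == 0L
  perBlock <- lapply(names(blockList), function(b) {
    idx <- blockList[[b]]
    if (any(constant[idx])) {
      warning("block ", b, ": ", sum(constant[idx]),
              " constant feature(s) excluded")
      idx <- idx[!constant[idx]]
    }
    if (length(idx) < 2L)
      return(data.frame(block_id = as.integer(b), n_pairs = 0L,
                        mean_rho = NA_real_))
    pr <- spearmanPairs(object, rownames(cnt)[idx], perClass = perClass,
                        log2 = log2)
    data.frame(block_id = as.integer(b), n_pairs = nrow(pr),
               mean_rho = mean(pr$rho))
  })
  perBlock <- do.call(rbind, perBlock)
  nWithin <- sum(perBlock$n_pairs)
  offPool <- setdiff(which(!constant), unlist(blockList))
  offMean <- NA_real_
  if (length(offPool) >= 2L && nWithin > 0L) {
    set.seed(stageSeed(seed, "offpairs"))
    nOff <- min(10L * nWithin, choose(length(offPool), 2L))
    rhos <- numeric(nOff)
    for (k in seq_len(nOff)) {
      pick <- sample(offPool, 2L)
      pr <- spearmanPairs(object, rownames(cnt)[pick], perClass = perClass,
                          log2 = log2)
      rhos[k] <- pr$rho
    }
    offMean <- mean(rhos)
  }
  list(within_block_mean = sum(perBlock$n_pairs * perBlock$mean_rho) /
         max(1L, nWithin),
       off_block_mean = offMean,
       per_block = perBlock)
}
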