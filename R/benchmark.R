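#' Assess a synthetic dataset against its input dataset
#'
#' Runs the full metric battery on one input / synthetic pair: Q-Q
#' concordance over library-size-matched sample pairs, dispersion-trend and
#' mean-variance-trend distances, feature-feature Spearman correlation
#' distance (25 sampled non-constant features per dataset), DEG counts from
#' the NB Wald test at `alpha` on both datasets, sign balance of the
#' synthetic dataset, and PCA-silhouette separability of both.  Comparing a
#' dataset with itself yields all-zero distances and equal DEG counts.
#'
#' @param input,synth [CountDataSet-class] objects with two-class labels.
#' @param name label of the generator that produced `synth`.
#' @param alpha FDR threshold for the DEG criterion (default 0.05).
#' @param seed root seed for every randomized step (feature subsampling,
#'   off-block pairs); the same child streams are used on both datasets.
#' @param n_pairs Q-Q sample pairs (default 5).
#' @param log2 compare distributions and correlations on `log2(count + 1)`
#'   (default `TRUE`).
#' @return a [MetricReport-class].
#' @examples
#' a <- makeFixture("ngssppg1_small", seed = 1)
#' rep <- assessPair(a, a, name = "self")
#' rep
#' @export
assessPair <- function(input, synth, name = "synthetic", alpha = 0.05,
                       seed = 1, n_pairs = 5L, log2 = TRUE) {
  stopifnot(is(input, "CountDataSet"), is(synth, "CountDataSet"))
  requireTwoClasses(input, 2L); requireTwoClasses(synth, 2L)
  qq <- qqCompare(input, synth, n_pairs = n_pairs, log2 = log2)
  dispI <- estimateDispersionsMoM(input)
  dispS <- estimateDispersionsMoM(synth)
  dd <- dispersionDistance(dispS, dispI)
  mvd <- meanVarianceDistance(meanVarianceTrend(synth), meanVarianceTrend(input))
  featI <- selectNonconstantFeatures(input, 25L, seed = seed)
  featS <- selectNonconstantFeatures(synth, 25L, seed = seed)
  rhoI <- spearmanPairs(input, featI, log2 = log2)$rho
  rhoS <- spearmanPairs(synth, featS, log2 = log2)$rho
  cd <- correlationDistance(rhoS, rhoI)
  resI <- nbWaldTest(input)
  resS <- nbWaldTest(synth)
  sb <- suppressWarnings(signBalance(resS, alpha))
  silI <- assessSeparability(input)$silhouette
  silS <- assessSeparability(synth)$silhouette
  new("MetricReport",
      generator = name,
      qq = qq$summary,
      dispersionDistance = dd,
      meanVarianceDistance = mvd,
      correlationDistance = cd,
      degCount = countDegs(resS, alpha),
      degCountInput = countDegs(resI, alpha),
      signBalance = sb,
      silhouetteSynth = silS,
      silhouetteInput = silI,
      settings = list(alpha = alpha, seed = seed, n_pairs = n_pairs,
                      log2_transform = log2,
                      qq_pairing = "sorted library size, evenly spaced ranks",
                      correlation_mode = "log2(count+1), per class, averaged",
                      dispersion_delta = 1e-3,
                      n_correlation_features = 25L))
}

setMethod("show", "MetricReport", function(object) {
  cat("MetricReport [", object@generator, "]\n", sep = "")
  cat(sprintf("  qq: slope %.3f, max|dq| %.4f, ks %.4f\n",
              object@qq[["slope"]], object@qq[["max_abs_deviation"]],
              object@qq[["ks_stat"]]))
  cat(sprintf("  dispersion dist %.4f | mean-variance dist %.4f | correlation dist %.4f\n",
              object@dispersionDistance, object@meanVarianceDistance,
              object@correlationDistance))
  cat(sprintf("  DEGs: %d (input %d) | sign balance %.3f\n",
              object@degCount, object@degCountInput, object@signBalance))
  cat(sprintf("  silhouette: %.3f (input %.3f)\n",
              object@silhouetteSynth, object@silhouetteInput))
})

#' Flatten a MetricReport to a plain list (JSON-ready)
#'
#' @param report a [MetricReport-class].
#' @return nested named list; `reportFromList()` restores the object, and
#'   the pair round-trips losslessly through `jsonlite`.
#' @export
reportToList <- function(report) {
  stopifnot(is(report, "MetricReport"))
  list(generator = report@generator,
       qq = as.list(report@qq),
       dispersion_distance = report@dispersionDistance,
       mean_variance_distance = report@meanVarianceDistance,
       correlation_distance = report@correlationDistance,
       deg_count = report@degCount,
       deg_count_input = report@degCountInput,
       sign_balance = report@signBalance,
       silhouette_synth = report@silhouetteSynth,
       silhouette_input = report@silhouetteInput,
       settings = report@settings)
}

#' @rdname reportToList
#' @param x a list as produced by `reportToList` (possibly after a JSON
#'   round trip).
#' @export
reportFromList <- function(x) {
  new("MetricReport",
      generator = x$generator,
      qq = unlist(x$qq),
      dispersionDistance = as.numeric(x$dispersion_distance),
      meanVarianceDistance = as.numeric(x$mean_variance_distance),
      correlationDistance = as.numeric(x$correlation_distance),
      degCount = as.integer(x$deg_count),
      degCountInput = as.integer(x$deg_count_input),
      signBalance = as.numeric(x$sign_balance),
      silhouetteSynth = as.numeric(x$silhouette_synth),
      silhouetteInput = as.numeric(x$silhouette_input),
      settings = as.list(x$settings))
}

# The per-criterion distances used for ranking.
criterionDistances <- function(report) {
  c(qq = unname(report@qq[["max_abs_deviation"]]),
    dispersion = report@dispersionDistance,
    mean_variance = report@meanVarianceDistance,
    correlation = report@correlationDistance,
    deg = abs(report@degCount - report@degCountInput),
    separability = abs(report@silhouetteSynth - report@silhouetteInput))
}

#' Rank generators per criterion
#'
#' Orders the assessed generators by ascending distance on each criterion
#' (`qq` = mean maximum absolute quantile deviation, `dispersion`,
#' `mean_variance`, `correlation`, `deg` = absolute difference of DEG
#' counts, `separability` = absolute silhouette difference).  Ties are
#' broken lexicographically by generator name.
#'
#' @param entries list of [MetricReport-class] objects (>= 1).
#' @return data.frame with columns `criterion`, `generator`, `distance`,
#'   `rank`.
#' @export
compareGenerators <- function(entries) {
  if (is(entries, "MetricReport")) entries <- list(entries)
  stopifnot(length(entries) >= 1L,
            all(vapply(entries, is, logical(1L), "MetricReport")))
  names <- vapply(entries, slot, character(1L), "generator")
  dist <- t(vapply(entries, criterionDistances, numeric(6L)))
  out <- do.call(rbind, lapply(colnames(dist), function(cr) {
    d <- dist[, cr]
    ord <- order(d, names)
    data.frame(criterion = cr, generator = names[ord],
               distance = unname(d[ord]), rank = seq_along(ord))
  }))
  rownames(out) <- NULL
  out
}

#' Write a benchmarking report directory
#'
#' Writes `report.json` (all entries plus the ranking and the settings
#' actually used), `ranking.tsv`, and a plain-text `log.txt`.
#'
#' @param entries list of [MetricReport-class] objects.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeBenchmarkReport <- function(entries, dir) {
  if (is(entries, "MetricReport")) entries <- list(entries)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ranking <- compareGenerators(entries)
  payload <- list(entries = lapply(entries, reportToList),
                  ranking = ranking)
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.table(ranking, file.path(dir, "ranking.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  log <- c(paste0("countsimbench ", as.character(utils::packageVersion("countsimbench"))),
           paste0("entries: ", paste(vapply(entries, slot, character(1L),
                                            "generator"), collapse = ", ")),
           "settings (first entry):",
           paste0("  ", names(entries[[1L]]@settings), " = ",
                  vapply(entries[[1L]]@settings, function(v)
                    paste(format(v), collapse = ","), character(1L))))
  writeLines(log, file.path(dir, "log.txt"))
  invisible(dir)
}
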