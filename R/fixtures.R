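#' Deterministic test and example datasets
#'
#' Small datasets generated in code, reproducible from `(name, seed)`:
#' \describe{
#'   \item{`tiny_counts`}{hand-written 6 x 4 matrix with one zero-median
#'     feature and one entry above a small truncation ceiling (1000).}
#'   \item{`null_nb`}{negative-binomial counts with no class effect
#'     (defaults `mu = 300`, `phi = 0.1`, 5000 features, 50 per class) —
#'     the type-I-error fixture.}
#'   \item{`two_blob`}{two well-separated classes (strong mean shift on a
#'     third of the features).}
#'   \item{`ngsspg1_small` / `ngsspg2_small`}{the simulator presets scaled
#'     to 500 features x 20 samples with all statistical settings kept
#'     (also accepted with the `ngssppg*` spelling).}
#' }
#'
#' @param name fixture name (above).
#' @param seed seed (default 1); ignored by `tiny_counts`.
#' @param nFeatures,nPerClass,mu,phi overrides for `null_nb`.
#' @return a [CountDataSet-class]; the simulator fixtures carry full
#'   ground truth.
#' @examples
#' makeFixture("tiny_counts")
#' @export
makeFixture <- function(name, seed = 1, nFeatures = 5000L, nPerClass = 50L,
                        mu = 300, phi = 0.1) {
  switch(name,
    tiny_counts = {
      m <- matrix(c(
         0L,  0L,   0L, 5L,    # zero-median feature, removed by the filter
         3L,  4L,   5L, 6L,
        10L, 12L,  11L, 9L,
         1L,  1L,   2L, 2L,
         7L,  5L, 5000L, 6L,   # 5000 exceeds the small ceiling of 1000
         2L,  3L,   2L, 4L),
        nrow = 6L, byrow = TRUE,
        dimnames = list(paste0("g", 1:6), paste0("s", 1:4)))
      CountDataSet(m, classLabels = c(1L, 1L, 2L, 2L),
                   metadata = list(truncation_ceiling = 1000))
    },
    null_nb = {
      set.seed(stageSeed(seed, "latent"))
      n <- 2L * as.integer(nPerClass)
      m <- matrix(rnbinom(as.integer(nFeatures) * n, mu = mu, size = 1 / phi),
                  nrow = as.integer(nFeatures), ncol = n)
      storage.mode(m) <- "integer"
      dimnames(m) <- list(paste0("gene_", seq_len(nrow(m))),
                          paste0("sample_", seq_len(ncol(m))))
      CountDataSet(m, classLabels = rep(c(1L, 2L), each = nPerClass),
                   metadata = list(mu = mu, phi = phi))
    },
    two_blob = {
      p <- simParams(nFeatures = 120, nPerClass = c(10, 10),
                     deFraction = 1 / 3, lfcDE = 3, sigma = 0.1,
                     nBlocks = 0, targetMeanCount = 200, seed = seed)
      simulateDataset(p, seed = seed)
    },
    ngsspg1_small = ,
    ngssppg1_small = simulateDataset("ngssppg1-small", seed = seed),
    ngsspg2_small = ,
    ngssppg2_small = simulateDataset("ngssppg2-small", seed = seed),
    stop("unknown fixture: '", name, "'")
  )
}
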