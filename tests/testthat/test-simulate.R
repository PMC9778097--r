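test_that("sigma = 0 collapses the latent draw onto the class means", {
  p <- simParams(nFeatures = 50, nPerClass = c(4, 4), deFraction = 0.1,
                 sigma = 0, nBlocks = 0, lfcDE = 1)
  lat <- simulateLogConcentrations(p, seed = 3)
  truth <- attr(lat, "truth")
  expect_equal(dim(lat), c(50L, 8L))
  nonDE <- setdiff(seq_len(50), truth$deIdx)
  expect_true(all(lat[nonDE, ] == p@baselineLogMean))
  expect_true(all(lat[truth$deIdx, truth$classLabels == 1L] == p@baselineLogMean))
  expect_equal(unique(as.numeric(lat[truth$deIdx, truth$classLabels == 2L])),
               p@baselineLogMean + log(2))
})

test_that("latent class means match for non-DE features and block correlation is recovered", {
  p <- simParams(nFeatures = 30, nPerClass = c(5000, 5000), deFraction = 0.2,
                 sigma = 0.4, blockSize = 5, blockRho = 0.4, nBlocks = 1)
  lat <- simulateLogConcentrations(p, seed = 5)
  truth <- attr(lat, "truth")
  cls <- truth$classLabels
  nonDE <- setdiff(seq_len(30), c(truth$deIdx, unlist(truth$blocks)))
  for (g in head(nonDE, 5)) {
    d <- mean(lat[g, cls == 2L]) - mean(lat[g, cls == 1L])
    se <- p@sigma * sqrt(2 / 5000)
    expect_lt(abs(d), 3 * se)
  }
  # empirical Pearson correlation of latent block rows approaches the design
  idx <- truth$blocks[[1L]]
  r <- cor(t(lat[idx, ]))
  expect_lt(abs(mean(r[upper.tri(r)]) - 0.4), 0.03)
})

test_that("depth calibration hits its fixed point and scales linearly", {
  p <- simParams(nFeatures = 400, nPerClass = c(20, 20), targetMeanCount = 300)
  lat <- simulateLogConcentrations(p, seed = 7)
  # fixed point: target equal to the uncalibrated pilot mean gives scale ~ 1
  set.seed(1); pilotMean <- mean(rpois(length(lat), exp(lat)))
  pFix <- simParams(nFeatures = 400, nPerClass = c(20, 20),
                    targetMeanCount = pilotMean)
  expect_lt(abs(calibrateDepth(pFix, seed = 7, latent = lat) - 1), 0.02)
  # doubling the target doubles the scale (Poisson mean linear in rate)
  a1 <- calibrateDepth(p, seed = 7, latent = lat)
  p2 <- simParams(nFeatures = 400, nPerClass = c(20, 20), targetMeanCount = 600)
  a2 <- calibrateDepth(p2, seed = 7, latent = lat)
  expect_lt(abs(a2 / a1 - 2), 0.04)
})

test_that("overall mean count lands within 1% of the target across presets and seeds", {
  for (preset in c("ngssppg1-small", "ngssppg2-small")) {
    for (sd in 1:3) {
      cds <- simulateDataset(preset, seed = sd)
      expect_lt(abs(mean(counts(cds)) - 300) / 300, 0.01)
    }
  }
})

test_that("Poisson sampling honours its contracts", {
  p <- simParams(nFeatures = 2000, nPerClass = c(25, 25), deFraction = 0,
                 sigma = 0, nBlocks = 0, baselineLogMean = log(50))
  lat <- simulateLogConcentrations(p, seed = 2)
  # latent constant at ln(lambda), scale 1: variance/mean ratio ~ 1 per gene
  cnt <- simulateCounts(lat, scale = 1, p, seed = 2)
  ratio <- apply(cnt, 1L, var) / rowMeans(cnt)
  expect_lt(abs(mean(ratio) - 1), 0.03)
  # scale 0 gives the all-zero matrix
  expect_true(all(simulateCounts(lat, scale = 0, p, seed = 2) == 0L))
  # fixed seed: bitwise identical; rate ceiling guards overflow
  expect_identical(simulateCounts(lat, 1, p, seed = 9),
                   simulateCounts(lat, 1, p, seed = 9))
  expect_error(simulateCounts(lat, 1e15, p, seed = 2), "ceiling")
})

test_that("the end-to-end pipeline is reproducible and fully labelled", {
  a <- simulateDataset("ngssppg1-small", seed = 11)
  b <- simulateDataset("ngssppg1-small", seed = 11)
  expect_identical(counts(a), counts(b))
  expect_identical(deFlags(a), deFlags(b))
  c <- simulateDataset("ngssppg1-small", seed = 12)
  expect_false(identical(counts(a), counts(c)))
  expect_identical(dim(a), c(500L, 20L))
  expect_identical(sum(deFlags(a)), 25L)
  expect_identical(as.integer(table(classLabels(a))), c(10L, 10L))
  # truth invariant: true_lfc is 0 exactly where de_flag is FALSE
  expect_true(all(trueLfc(a)[!deFlags(a)] == 0))
  expect_true(all(trueLfc(a)[deFlags(a)] == 1))
  expect_identical(sum(!is.na(blockIds(a))), 5L)
  # no DE design
  p0 <- simParams(nFeatures = 60, nPerClass = c(4, 4), deFraction = 0,
                  nBlocks = 0)
  z <- simulateDataset(p0, seed = 1)
  expect_false(any(deFlags(z)))
  expect_true(all(trueLfc(z) == 0))
})

test_that("larger latent noise produces larger log-count variance", {
  a <- simulateDataset("ngssppg1-small", seed = 6)
  b <- simulateDataset("ngssppg2-small", seed = 6)
  va <- median(apply(log1p(counts(a)), 1L, var))
  vb <- median(apply(log1p(counts(b)), 1L, var))
  expect_gt(vb, va)
})

test_that("empirical DE effect converges to the designed log2 fold change", {
  p <- simParams(nFeatures = 100, nPerClass = c(2000, 2000), deFraction = 0.2,
                 sigma = 0.4, nBlocks = 1, lfcDE = 1)
  cds <- simulateDataset(p, seed = 8)
  cls <- classLabels(cds)
  de <- deFlags(cds)
  ratio <- log2(rowMeans(counts(cds)[de, cls == 2L]) /
                rowMeans(counts(cds)[de, cls == 1L]))
  expect_true(all(abs(ratio - 1) < 0.1))
})

test_that("with lfcDE = 0 the two class-conditional distributions are exchangeable", {
  p <- simParams(nFeatures = 300, nPerClass = c(50, 50), nGlobalMarkers = 0L,
                 lfcDE = 0, nBlocks = 1, seed = 4)
  cds <- simulateDataset(p, seed = 4)
  cls <- classLabels(cds)
  pv <- apply(counts(cds), 1L, function(r)
    suppressWarnings(stats::ks.test(r[cls == 1L], r[cls == 2L]))$p.value)
  rej <- mean(pv < 0.05)
  expect_gte(rej, 0.005)  # discreteness makes the KS test conservative
  expect_lte(rej, 0.10)
})

test_that("heterogeneous markers shift only the designated class-1 subgroups", {
  p <- simParams(nFeatures = 40, nPerClass = c(12, 6), nSubgroupsClass1 = 3,
                 deFraction = 0, nHeteroMarkers = 5, sigma = 0, nBlocks = 0,
                 lfcDE = 1)
  lat <- simulateLogConcentrations(p, seed = 13)
  truth <- attr(lat, "truth")
  expect_length(truth$heteroSubgroups, 2L)  # ceiling(3/2)
  shifted <- truth$classLabels == 1L & truth$subgroup %in% truth$heteroSubgroups
  h <- truth$heteroIdx[1L]
  expect_true(all(lat[h, shifted] == log(2)))
  expect_true(all(lat[h, !shifted] == 0))
})
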