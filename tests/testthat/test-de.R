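test_that("median-of-ratios size factors match analytic cases and an oracle", {
  m <- matrix(rep(c(5L, 9L, 30L), 3), 3, 3,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
  expect_equal(unname(sizeFactorsMoR(m)), rep(1, 3))
  # column 2 = 2 x column 1, all positive: factors (1/sqrt(2), sqrt(2))
  m2 <- cbind(s1 = c(4L, 10L, 26L), s2 = c(8L, 20L, 52L))
  rownames(m2) <- paste0("g", 1:3)
  expect_equal(unname(sizeFactorsMoR(m2)), c(1 / sqrt(2), sqrt(2)))
  set.seed(14)
  r <- matrix(rpois(200, 50) + 1L, 20, 10,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  expect_equal(unname(sizeFactorsMoR(r)), oracleSizeFactors(r))
  # all-zero-containing features only: falls back with a warning
  z <- rbind(c(0L, 3L), c(4L, 0L))
  dimnames(z) <- list(c("g1", "g2"), c("s1", "s2"))
  expect_warning(sf <- sizeFactorsMoR(z), "positive in every sample")
  expect_true(all(sf > 0))
})

test_that("the Wald test degenerates correctly and detects huge effects", {
  # identical class profiles: lfc 0, wald 0, p 1
  col <- c(10L, 40L, 200L, 7L)
  m <- matrix(rep(col, 4), 4, 4,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:4)))
  res <- suppressWarnings(nbWaldTest(CountDataSet(m, classLabels = c(1, 1, 2, 2))))
  expect_equal(res$lfc, rep(0, 4))
  expect_equal(res$wald, rep(0, 4))
  expect_equal(res$pvalue, rep(1, 4))
  # enormous effect on a few genes, tiny dispersion: q far below 1e-6
  set.seed(20)
  G <- 200
  mu2 <- rep(100, G); mu2[1:5] <- 800
  g1 <- matrix(rnbinom(G * 50, mu = 100, size = 1e4), G, 50)
  g2 <- matrix(rnbinom(G * 50, mu = mu2, size = 1e4), G, 50)
  cds <- CountDataSet(cbind(g1, g2), classLabels = rep(1:2, each = 50))
  resBig <- nbWaldTest(cds)
  expect_true(all(resBig$qvalue[1:5] < 1e-6))
  expect_true(all(resBig$lfc[1:5] > 2.5))
  expect_error(nbWaldTest(CountDataSet(m, classLabels = c(1, 2, 2, 2))),
               ">= 2 samples per class")
})

test_that("swapping class labels negates effects, and normalization absorbs depth", {
  cds <- makeFixture("ngssppg1_small", seed = 7)
  res <- nbWaldTest(cds)
  swapped <- CountDataSet(counts(cds), classLabels = 3L - classLabels(cds))
  resSw <- nbWaldTest(swapped)
  expect_equal(resSw$lfc, -res$lfc)
  expect_equal(resSw$pvalue, res$pvalue)
  # scaling one sample's counts is absorbed by its re-estimated size factor
  # (exact up to the pseudocount interacting with the c^(1/n) renormalization
  # of the geometric means)
  cnt <- counts(cds); cnt[, 3] <- cnt[, 3] * 3L
  resScaled <- nbWaldTest(CountDataSet(cnt, classLabels = classLabels(cds)))
  expect_equal(resScaled$lfc, res$lfc, tolerance = 1e-4)
  expect_equal(resScaled$pvalue, res$pvalue, tolerance = 1e-4)
})

test_that("BH adjustment equals the brute-force step-up on random p-vectors", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  for (i in 1:10) {
    set.seed(i)
    p <- runif(sample(5:200, 1))^sample(1:3, 1)
    q <- bhAdjust(p)
    expect_equal(q, oracleBH(p))
    for (alpha in c(0.01, 0.05, 0.2)) {
      expect_identical(q <= alpha, oracleBHReject(p, alpha))
    }
  }
  expect_error(bhAdjust(c(0.5, 1.2)))
})

test_that("DEG counting and volcano classification follow their thresholds", {
  cds <- makeFixture("ngssppg1_small", seed = 7)
  res <- nbWaldTest(cds)
  expect_identical(countDegs(res, alpha = 0), 0L)
  expect_identical(countDegs(res, alpha = 1), nrow(res))
  expect_identical(countDegs(res), sum(res$qvalue <= 0.05))
  vt <- volcanoTable(res)
  expect_setequal(unique(vt$class),
                  intersect(c("nonsig", "sig_small_fc", "sig_up", "sig_down"),
                            unique(vt$class)))
  sig <- res$pvalue < 0.05
  expect_identical(vt$class == "sig_up", unname(sig & res$lfc > 1))
  expect_identical(vt$class == "sig_down", unname(sig & res$lfc < -1))
  expect_identical(vt$class == "nonsig", unname(!sig))
  expect_true(all(vt$neg_log10_p <= 350))
})

test_that("sign balance distinguishes one-sided from symmetric designs", {
  # strong symmetric effects: half up, half down, all significant
  set.seed(99)
  G <- 200; n <- 30
  lfc <- rep(c(1, -1), each = G / 2)
  m1 <- matrix(rnbinom(G * n, mu = 300, size = 50), G, n)
  m2 <- matrix(rnbinom(G * n, mu = 300 * 2^lfc, size = 50), G, n)
  cds <- CountDataSet(cbind(m1, m2), classLabels = rep(1:2, each = n))
  res <- nbWaldTest(cds)
  expect_gt(countDegs(res), 100)
  expect_lt(abs(signBalance(res) - 0.5), 0.05)
  # the simulator's designed DE is over-expression only
  sim <- makeFixture("ngssppg1_small", seed = 2)
  resSim <- nbWaldTest(sim)
  expect_gt(signBalance(resSim), 0.9)
  # nothing significant: undefined, flagged
  null <- makeFixture("null_nb", seed = 3, nFeatures = 100, nPerClass = 10)
  expect_warning(sb <- signBalance(nbWaldTest(null), alpha = 1e-12), "undefined")
  expect_true(is.nan(sb))
})

test_that("recovery against ground truth uses the stated conventions", {
  sim <- makeFixture("ngssppg1_small", seed = 2)
  res <- nbWaldTest(sim)
  rec <- degRecovery(res, sim)
  expect_gte(rec$sensitivity, 0); expect_lte(rec$sensitivity, 1)
  expect_gte(rec$observed_fdr, 0)
  # zero discoveries: sensitivity 0, fdr 0 by convention
  rec0 <- degRecovery(res, sim, alpha = 0)
  expect_identical(rec0$sensitivity, 0)
  expect_identical(rec0$observed_fdr, 0)
  # a perfect caller scores sensitivity 1, fdr 0
  fake <- res
  fake$qvalue <- ifelse(deFlags(sim), 0, 1)
  recP <- degRecovery(fake, sim)
  expect_equal(recP$sensitivity, 1)
  expect_equal(recP$observed_fdr, 0)
  expect_error(degRecovery(res, rep(FALSE, nrow(res))), "no DE features")
})
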