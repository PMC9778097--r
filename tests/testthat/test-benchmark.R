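fakeReport <- function(name, d) {
  new("MetricReport", generator = name,
      qq = c(slope = 1, intercept = 0, max_abs_deviation = d[1], ks_stat = 0),
      dispersionDistance = d[2], meanVarianceDistance = d[3],
      correlationDistance = d[4], degCount = as.integer(100 + d[5]),
      degCountInput = 100L, signBalance = 0.5,
      silhouetteSynth = 0.5 + d[6], silhouetteInput = 0.5,
      settings = list())
}

test_that("self-comparison is the all-zero fixed point of the assessment", {
  cds <- makeFixture("ngssppg1_small", seed = 1)
  rep <- assessPair(cds, cds, name = "self", seed = 4)
  expect_equal(unname(rep@qq[["slope"]]), 1)
  expect_equal(unname(rep@qq[["max_abs_deviation"]]), 0)
  expect_equal(unname(rep@qq[["ks_stat"]]), 0)
  expect_equal(rep@dispersionDistance, 0)
  expect_equal(rep@meanVarianceDistance, 0)
  expect_equal(rep@correlationDistance, 0)
  expect_identical(rep@degCount, rep@degCountInput)
  expect_equal(rep@silhouetteSynth, rep@silhouetteInput)
})

test_that("constructed perturbations are detected by the right criterion", {
  cds <- makeFixture("ngssppg1_small", seed = 1)
  # global scaling of one class shifts the count distribution off the diagonal
  cnt <- counts(cds)
  cnt[, classLabels(cds) == 2L] <- cnt[, classLabels(cds) == 2L] * 2L
  doubled <- CountDataSet(cnt, classLabels = classLabels(cds))
  repD <- assessPair(cds, doubled, name = "doubled")
  expect_gt(unname(repD@qq[["max_abs_deviation"]]), 0.1)
  # a feature-specific class effect (not absorbed by normalization)
  cnt2 <- counts(cds)
  boost <- seq_len(100)
  cnt2[boost, classLabels(cds) == 2L] <- cnt2[boost, classLabels(cds) == 2L] * 4L
  shifted <- CountDataSet(cnt2, classLabels = classLabels(cds))
  repS <- assessPair(cds, shifted, name = "shifted")
  expect_gt(repS@degCount, repS@degCountInput)
})

criterionDistances_ <- function(r) {
  c(r@qq[["max_abs_deviation"]], r@dispersionDistance, r@meanVarianceDistance,
    r@correlationDistance, abs(r@degCount - r@degCountInput),
    abs(r@silhouetteSynth - r@silhouetteInput))
}

test_that("reports serialize to JSON and back without loss", {
  cds <- makeFixture("ngssppg1_small", seed = 3)
  rep <- assessPair(cds, cds, name = "roundtrip", seed = 2)
  json <- jsonlite::toJSON(reportToList(rep), auto_unbox = TRUE, digits = NA)
  back <- reportFromList(jsonlite::fromJSON(json, simplifyVector = FALSE))
  expect_identical(back@generator, rep@generator)
  expect_equal(back@qq, rep@qq)
  expect_equal(criterionDistances_(back), criterionDistances_(rep))
  expect_identical(back@degCount, rep@degCount)
  expect_equal(back@signBalance, rep@signBalance)
})

test_that("generator ranking sorts by distance with lexicographic ties", {
  single <- compareGenerators(fakeReport("only", rep(0.2, 6)))
  expect_true(all(single$rank == 1L))
  # dominance: A below B on every criterion
  rk <- compareGenerators(list(fakeReport("B", rep(0.5, 6)),
                               fakeReport("A", rep(0.1, 6))))
  expect_true(all(rk$generator[rk$rank == 1L] == "A"))
  # ties broken lexicographically
  tie <- compareGenerators(list(fakeReport("zeta", rep(0.3, 6)),
                                fakeReport("alpha", rep(0.3, 6))))
  expect_true(all(tie$generator[tie$rank == 1L] == "alpha"))
  # random tables equal a brute-force sort oracle
  set.seed(40)
  reps <- lapply(c("g1", "g2", "g3", "g4"),
                 function(nm) fakeReport(nm, round(runif(6), 3)))
  rk2 <- compareGenerators(reps)
  for (cr in unique(rk2$criterion)) {
    sub <- rk2[rk2$criterion == cr, ]
    d <- vapply(reps, function(r) {
      i <- match(cr, c("qq", "dispersion", "mean_variance", "correlation",
                       "deg", "separability"))
      criterionDistances_(r)[i]
    }, numeric(1L))
    nm <- vapply(reps, slot, character(1L), "generator")
    expect_identical(sub$generator, nm[order(d, nm)])
    expect_identical(sub$rank, seq_along(reps))
  }
})

test_that("the CLI drives the full pipeline and reports failures by status", {
  d <- withr::local_tempdir()
  simDir <- file.path(d, "sim")
  expect_identical(suppressMessages(runCLI(c("simulate", "--preset", "ngssppg1-small",
                            "--seed", "5", "--out", simDir))), 0L)
  expect_true(file.exists(file.path(simDir, "counts.tsv")))
  expect_true(file.exists(file.path(simDir, "truth.tsv")))
  # de test on the written fixtures
  deDir <- file.path(d, "de")
  expect_identical(suppressMessages(runCLI(c("de", "test",
                            "--counts", file.path(simDir, "counts.tsv"),
                            "--annotation", file.path(simDir, "annotation.tsv"),
                            "--truth", file.path(simDir, "truth.tsv"),
                            "--out", deDir))), 0L)
  deSum <- jsonlite::read_json(file.path(deDir, "de_summary.json"))
  expect_true(deSum$n_deg > 0)
  expect_true(deSum$observed_fdr <= 0.2)
  # self-assessment through files: all-zero distances
  aDir <- file.path(d, "assess")
  expect_identical(suppressMessages(runCLI(c("assess",
                            "--input", file.path(simDir, "counts.tsv"),
                            "--synthetic", file.path(simDir, "counts.tsv"),
                            "--ann-input", file.path(simDir, "annotation.tsv"),
                            "--ann-synthetic", file.path(simDir, "annotation.tsv"),
                            "--name", "self", "--seed", "1",
                            "--out", aDir))), 0L)
  payload <- jsonlite::read_json(file.path(aDir, "report.json"),
                                 simplifyVector = FALSE)
  entry <- payload$entries[[1L]]
  expect_equal(entry$dispersion_distance, 0)
  expect_equal(entry$correlation_distance, 0)
  expect_equal(entry$qq$max_abs_deviation, 0)
  expect_identical(entry$deg_count, entry$deg_count_input)
  # compare re-ranks written reports
  cDir <- file.path(d, "cmp")
  expect_identical(suppressMessages(runCLI(c("compare", "--reports",
                            file.path(aDir, "report.json"), "--out", cDir))), 0L)
  expect_true(file.exists(file.path(cDir, "ranking.tsv")))
  # prep subcommands
  pDir <- file.path(d, "prep.tsv")
  expect_identical(suppressMessages(runCLI(c("prep", "filter-zero-median",
                            "--counts", file.path(simDir, "counts.tsv"),
                            "--out", pDir))), 0L)
  expect_true(file.exists(pDir))
  # failures: missing file, bad subcommand -> nonzero status with a message
  expect_message(st <- runCLI(c("assess", "--input", "nope.tsv",
                                "--synthetic", "nope.tsv",
                                "--ann-input", "a", "--ann-synthetic", "b",
                                "--out", d)), "not found")
  expect_identical(st, 1L)
  expect_message(st2 <- runCLI("frobnicate"), "unknown subcommand")
  expect_identical(st2, 1L)
})
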