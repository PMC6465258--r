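# small precomputed feature pair shared across sweep tests
makePair <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- phantomConfig(imageShape = c(3L, 60L, 48L))
    tr <- generateCohort(cfg, 16, 16, seed = 101L)
    te <- generateCohort(cfg, 8, 10, seed = 102L)
    ppt <- marrowtex:::preprocessCohort(tr, 1L, 100L)
    ppe <- marrowtex:::preprocessCohort(te, 1L, 100L)
    cache <<- marrowtex:::buildFeaturePair(ppt$subjects, ppt$masks,
                                           ppe$subjects, ppe$masks, 1L)
    cache
  }
})

smallGrid <- list(C = 2^c(1, 5), gamma = 2^c(-7, -3))

test_that("single repetition aggregates collapse to the observed value", {
  pair <- makePair()
  sw <- trainingSizeSweep(pair$train, pair$test, sizes = 16L,
                          repetitions = 1L, Cgrid = smallGrid$C,
                          gammaGrid = smallGrid$gamma, seed = 1L)
  s <- sw$summary
  for (met in c("CA", "SE", "SP", "AUC")) {
    v <- s$value[s$metric == met]
    names(v) <- s$stat[s$metric == met]
    expect_identical(unname(v["highest"]), unname(v["lowest"]))
    expect_identical(unname(v["highest"]), unname(v["mean"]))
    expect_identical(unname(v["sd"]), 0)
  }
})

test_that("summary aggregates are recomputable from per-repetition records", {
  pair <- makePair()
  sw <- trainingSizeSweep(pair$train, pair$test, sizes = c(8L, 16L),
                          repetitions = 3L, Cgrid = smallGrid$C,
                          gammaGrid = smallGrid$gamma, seed = 2L)
  rec <- sw$records
  expect_identical(nrow(rec), 6L)
  for (sz in c(8L, 16L)) {
    d <- rec[rec$size == sz, ]
    s <- sw$summary[sw$summary$size == sz, ]
    expect_equal(s$value[s$metric == "CA" & s$stat == "mean"], mean(d$CA))
    expect_equal(s$value[s$metric == "CA" & s$stat == "sd"], sd(d$CA))
    expect_equal(s$value[s$metric == "AUC" & s$stat == "highest"],
                 max(d$AUC))
  }
  expect_error(trainingSizeSweep(pair$train, pair$test, sizes = 1000L,
                                 repetitions = 1L), "exceeds")
})

test_that("sweeps rerun identically under the same master seed", {
  pair <- makePair()
  run <- function() trainingSizeSweep(pair$train, pair$test, sizes = 16L,
                                      repetitions = 2L,
                                      Cgrid = smallGrid$C,
                                      gammaGrid = smallGrid$gamma, seed = 7L)
  expect_identical(run()$records, run()$records)
  fp <- list(`1` = pair)
  k1 <- kernelDimensionSweep(fp, kernels = "rbf", trainSize = 16L,
                             Cgrid = smallGrid$C,
                             gammaGrid = smallGrid$gamma, seed = 5L)
  k2 <- kernelDimensionSweep(fp, kernels = "rbf", trainSize = 16L,
                             Cgrid = smallGrid$C,
                             gammaGrid = smallGrid$gamma, seed = 5L)
  expect_identical(k1, k2)
  expect_identical(nrow(k1), 1L)
})

test_that("simulated readers hit their operating point", {
  truth <- rep(c(0L, 1L), each = 5000L)
  s <- simulateReaders(truth, 0.8, 0.8, seed = 3L)
  expect_true(all(s %in% 0:4))
  lab <- binarizeScores(s)
  se <- mean(lab[truth == 1L])
  sp <- mean(1 - lab[truth == 0L])
  expect_lt(abs(se - 0.8), 0.02)
  expect_lt(abs(sp - 0.8), 0.02)
  # perfect reader reproduces the truth after binarization
  perfect <- simulateReaders(truth, 1, 1, seed = 4L)
  expect_identical(binarizeScores(perfect), truth)
  expect_identical(simulateReaders(truth, 0.7, 0.9, seed = 9L),
                   simulateReaders(truth, 0.7, 0.9, seed = 9L))
  expect_error(simulateReaders(truth, 0, 0.5), "sensitivityTarget")
})

test_that("the full experiment runs end-to-end and writes its reports", {
  cfg <- experimentConfig(
    phantom = phantomConfig(imageShape = c(3L, 60L, 48L)),
    nTrainControl = 10L, nTrainDiseased = 10L,
    nTestControl = 5L, nTestDiseased = 6L,
    kernels = "rbf", sliceSettings = 1L,
    trainingSizes = c(8L, 12L, 16L, 20L), repetitions = 2L,
    Cgrid = smallGrid$C, gammaGrid = smallGrid$gamma,
    erosionRadius = 1L, maxIters = 100L, seed = 42L)
  outDir <- file.path(tempdir(), "mtx-exp")
  res <- runFullExperiment(cfg, outDir)
  for (f in c("fig1_data.csv", "table1.csv", "table1_records.csv",
              "table2.csv", "fig3_points.csv", "run_log.json"))
    expect_true(file.exists(file.path(outDir, f)))
  expect_identical(nrow(res$fig1), 1L)
  expect_identical(nrow(res$sizeSweep$records), 8L)
  expect_identical(nrow(res$table2), 3L)
  expect_true(all(c("mcnemarR1", "kappaR2", "deLongR1") %in%
                    names(res$comparison)))
  # determinism of persisted outputs
  outDir2 <- file.path(tempdir(), "mtx-exp2")
  runFullExperiment(cfg, outDir2)
  for (f in c("fig1_data.csv", "table1.csv", "table2.csv"))
    expect_identical(readLines(file.path(outDir, f)),
                     readLines(file.path(outDir2, f)))
})
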