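#' Experiment configuration
#'
#' Bundles the phantom configuration and the experiment design: cohort
#' composition (training 180:180 control:diseased, test 45:62 by default),
#' kernels, slice settings, training-size sweep, repetition count and the
#' master seed that determines every source of randomness (cohort draws,
#' fold splits, subset draws, reader simulation).
#'
#' @param phantom a [PhantomConfig-class].
#' @param nTrainControl,nTrainDiseased,nTestControl,nTestDiseased cohort
#'   composition.
#' @param kernels kernel kinds to sweep.
#' @param sliceSettings feature dimensions as slice counts (subset of
#'   1, 3, 9).
#' @param trainingSizes total training sizes for the size sweep (balanced
#'   draws).
#' @param repetitions repeated random draws per size (default 30).
#' @param Cgrid,gammaGrid grid-search ranges.
#' @param erosionRadius,maxIters GrowCut preprocessing parameters.
#' @param seed master seed.
#' @return a validated `ExperimentConfig` list.
#' @export
experimentConfig <- function(phantom = phantomConfig(),
                             nTrainControl = 180L, nTrainDiseased = 180L,
                             nTestControl = 45L, nTestDiseased = 62L,
                             kernels = c("poly3", "tanh", "rbf"),
                             sliceSettings = c(1L, 3L, 9L),
                             trainingSizes = c(180L, 240L, 300L, 360L),
                             repetitions = 30L,
                             Cgrid = defaultGrids()$C,
                             gammaGrid = defaultGrids()$gamma,
                             erosionRadius = 2L, maxIters = 200L,
                             seed = 1L) {
  stopifnot(repetitions >= 1L,
            max(trainingSizes) <= nTrainControl + nTrainDiseased,
            all(sliceSettings %in% c(1L, 3L, 9L)))
  structure(list(phantom = phantom,
                 nTrainControl = nTrainControl,
                 nTrainDiseased = nTrainDiseased,
                 nTestControl = nTestControl,
                 nTestDiseased = nTestDiseased,
                 kernels = kernels,
                 sliceSettings = as.integer(sliceSettings),
                 trainingSizes = as.integer(trainingSizes),
                 repetitions = as.integer(repetitions),
                 Cgrid = Cgrid, gammaGrid = gammaGrid,
                 erosionRadius = as.integer(erosionRadius),
                 maxIters = as.integer(maxIters),
                 seed = as.integer(seed)),
            class = "ExperimentConfig")
}

# generate + preprocess + featurize a train/test pair at one slice setting;
# returns unscaled FeatureMatrix objects (window fitted on the training
# cohort)
buildFeaturePair <- function(cohortTrain, masksTrain, cohortTest, masksTest,
                             nSlices, nLevels = 6L) {
  spec <- computeMinWindow(cohortTrain, masksTrain, nLevels = nLevels,
                           nSlices = nSlices)
  fv <- function(subjects, masks)
    lapply(seq_along(subjects), function(i)
      extractFeatureVector(subjects[[i]], masks[[i]], spec))
  train <- assembleMatrix(fv(cohortTrain, masksTrain),
                          vapply(cohortTrain, diseaseStatus, integer(1)))
  test <- assembleMatrix(fv(cohortTest, masksTest),
                         vapply(cohortTest, diseaseStatus, integer(1)))
  list(spec = spec, train = train, test = test)
}

# preprocess a whole cohort; returns list(subjects = normalized, masks)
preprocessCohort <- function(cohort, erosionRadius = 2L, maxIters = 200L) {
  out <- lapply(cohort, preprocessSubject, erosionRadius = erosionRadius,
                maxIters = maxIters)
  list(subjects = lapply(out, `[[`, "subject"),
       masks = lapply(out, `[[`, "mask"))
}

# balanced class subset of a given total size, reproducible
balancedSubset <- function(labels, size, seed) {
  stopifnot(size %% 2L == 0L)
  half <- size %/% 2L
  withSeed(seed, function() {
    c(sample(which(labels == 0L), half), sample(which(labels == 1L), half))
  })
}

subsetFeatureMatrix <- function(fm, idx) {
  initialize(fm, x = fm@x[idx, , drop = FALSE], labels = fm@labels[idx],
             subjectIds = fm@subjectIds[idx], scaled = FALSE,
             colMin = numeric(), colMax = numeric())
}

# one full train/evaluate pass: scale, grid search, final model, test
# metrics
trainEvaluate <- function(trainFM, testFM, kind, Cgrid, gammaGrid, seed) {
  sc <- minmaxScale(trainFM, list(testFM))
  gs <- gridSearchCV(sc$train, kind, Cgrid, gammaGrid, seed = seed)
  model <- trainSvm(sc$train, gs$best)
  predTr <- predictSvm(model, sc$train)
  predTe <- predictSvm(model, sc$others[[1]])
  mTr <- confusionMetrics(predTr$label, trainFM@labels)
  mTe <- confusionMetrics(predTe$label, testFM@labels)
  aucTe <- rocAuc(predTe$score, testFM@labels)
  list(best = gs$best, cvAccuracy = gs$cvAccuracy,
       train = mTr, test = mTe, testAuc = aucTe,
       testPred = predTe)
}

#' Kernel-by-dimension sweep at a fixed training size
#'
#' For every kernel and slice setting, draws one fixed balanced training
#' subset (default 180 subjects), runs grid-search + 5-fold CV, trains the
#' final model and evaluates on the fixed held-out test set.
#'
#' @param featurePairs named list (one per slice setting) of
#'   `list(train=, test=)` unscaled [FeatureMatrix-class] pairs.
#' @param kernels kernel kinds.
#' @param trainSize fixed training subset size.
#' @param Cgrid,gammaGrid grid ranges.
#' @param seed master seed.
#' @return data.frame of per-condition train/test accuracy, sensitivity,
#'   specificity and test AUC.
#' @export
kernelDimensionSweep <- function(featurePairs, kernels = c("poly3", "tanh",
                                                           "rbf"),
                                 trainSize = 180L,
                                 Cgrid = defaultGrids()$C,
                                 gammaGrid = defaultGrids()$gamma,
                                 seed = 1L) {
  rows <- list()
  ctr <- 0L
  for (ns in names(featurePairs)) {
    pair <- featurePairs[[ns]]
    idx <- balancedSubset(pair$train@labels, trainSize,
                          deriveSeed(seed, 7000L))
    sub <- subsetFeatureMatrix(pair$train, idx)
    for (k in kernels) {
      ctr <- ctr + 1L
      r <- trainEvaluate(sub, pair$test, k, Cgrid, gammaGrid,
                         deriveSeed(seed, 7100L + ctr))
      rows[[length(rows) + 1L]] <- data.frame(
        kernel = k, nSlices = as.integer(ns),
        dimension = ncol(pair$train@x), trainSize = trainSize,
        C = r$best@C, gamma = r$best@gamma,
        cvAccuracy = r$cvAccuracy,
        trainCA = r$train$accuracy$estimate,
        trainSE = r$train$sensitivity$estimate,
        testCA = r$test$accuracy$estimate,
        testSE = r$test$sensitivity$estimate,
        testSP = r$test$specificity$estimate,
        testAUC = r$testAuc$auc,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Training-size sweep with repeated random draws
#'
#' For every training size, `repetitions` balanced random subsets are drawn
#' from the training population (per-repetition seeds derived from the
#' master seed by a counter scheme, so conditions can run in any order);
#' each is grid-searched, trained and evaluated on the fixed test set.
#' Aggregates report highest, lowest and mean (SD) per size; SD is 0 for a
#' single repetition.
#'
#' @param trainFM,testFM unscaled [FeatureMatrix-class] objects.
#' @param sizes training sizes (even, balanced draws).
#' @param repetitions draws per size.
#' @param kind kernel kind for the final model (default `"rbf"`).
#' @param Cgrid,gammaGrid grid ranges.
#' @param seed master seed.
#' @return list: `records` (per-repetition data.frame), `summary`
#'   (aggregates per size).
#' @export
trainingSizeSweep <- function(trainFM, testFM, sizes, repetitions = 30L,
                              kind = "rbf", Cgrid = defaultGrids()$C,
                              gammaGrid = defaultGrids()$gamma, seed = 1L) {
  if (any(sizes > length(trainFM@labels)))
    stop("training size exceeds available cohort")
  rows <- list()
  for (si in seq_along(sizes)) {
    size <- sizes[si]
    for (rep_ in seq_len(repetitions)) {
      ctr <- si * 1000L + rep_
      idx <- balancedSubset(trainFM@labels, size, deriveSeed(seed, ctr))
      sub <- subsetFeatureMatrix(trainFM, idx)
      r <- trainEvaluate(sub, testFM, kind, Cgrid, gammaGrid,
                         deriveSeed(seed, 500000L + ctr))
      rows[[length(rows) + 1L]] <- data.frame(
        size = size, repetition = rep_,
        CA = r$test$accuracy$estimate,
        SE = r$test$sensitivity$estimate,
        SP = r$test$specificity$estimate,
        AUC = r$testAuc$auc,
        stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, rows)
  agg <- function(v) c(highest = max(v), lowest = min(v), mean = mean(v),
                       sd = if (length(v) > 1L) sd(v) else 0)
  summary <- do.call(rbind, lapply(split(records, records$size), function(d) {
    data.frame(size = d$size[1],
               metric = rep(c("CA", "SE", "SP", "AUC"), each = 4L),
               stat = rep(c("highest", "lowest", "mean", "sd"), times = 4L),
               value = c(agg(d$CA), agg(d$SE), agg(d$SP), agg(d$AUC)),
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  list(records = records, summary = summary)
}

#' Simulate ordinal reader confidence scores
#'
#' Generates five-level scores (0 definitely absent .. 4 definitely present)
#' whose binarized labels (3--4 positive) hit the requested sensitivity and
#' specificity in expectation, with graded confidence: correct calls get
#' extreme scores more often than boundary scores.
#'
#' @param truth binary 0/1 vector.
#' @param sensitivityTarget,specificityTarget probabilities in (0, 1), or
#'   exactly 1 for a perfect reader.
#' @param seed RNG seed.
#' @return integer scores in 0..4.
#' @export
simulateReaders <- function(truth, sensitivityTarget, specificityTarget,
                            seed = 1L) {
  stopifnot(sensitivityTarget > 0, sensitivityTarget <= 1,
            specificityTarget > 0, specificityTarget <= 1)
  truth <- as.integer(truth)
  withSeed(seed, function() {
    vapply(truth, function(t) {
      callPositive <- if (t == 1L) runif(1) < sensitivityTarget
      else runif(1) >= specificityTarget
      if (callPositive) sample(3:4, 1L, prob = c(0.45, 0.55))
      else sample(0:2, 1L, prob = c(0.45, 0.35, 0.20))
    }, integer(1))
  })
}

#' Run the full experiment end-to-end
#'
#' Generates train and test cohorts, preprocesses them (disk normalization +
#' GrowCut), featurizes at each slice setting, runs the kernel-by-dimension
#' sweep and the training-size sweep, simulates two readers on the test set,
#' computes the comparison statistics (Wilson CIs, McNemar, kappa, DeLong),
#' fits the learning curve to the size-sweep mean accuracies, and writes the
#' report files (`fig1_data.csv`, `table1.csv`, `table2.csv`,
#' `fig3_points.csv`, `run_log.json`) to `outDir`.
#'
#' @param config an `ExperimentConfig` from [experimentConfig].
#' @param outDir output directory (created if missing); `NULL` skips file
#'   output.
#' @return invisible list with all intermediate and final results.
#' @export
runFullExperiment <- function(config, outDir = NULL) {
  seed <- config$seed
  logLines <- list()
  note <- function(stage, ...) {
    logLines[[length(logLines) + 1L]] <<-
      list(stage = stage, detail = paste0(...), seed = seed)
  }
  note("simulate", "generating cohorts")
  trainCohort <- generateCohort(config$phantom, config$nTrainControl,
                                config$nTrainDiseased,
                                seed = deriveSeed(seed, 1L))
  testCohort <- generateCohort(config$phantom, config$nTestControl,
                               config$nTestDiseased,
                               seed = deriveSeed(seed, 2L))
  note("preprocess", "disk normalization + GrowCut")
  trainPP <- preprocessCohort(trainCohort, config$erosionRadius,
                              config$maxIters)
  testPP <- preprocessCohort(testCohort, config$erosionRadius,
                             config$maxIters)
  note("featurize", "slice settings: ",
       paste(config$sliceSettings, collapse = ","))
  featurePairs <- list()
  for (ns in config$sliceSettings) {
    featurePairs[[as.character(ns)]] <-
      buildFeaturePair(trainPP$subjects, trainPP$masks,
                       testPP$subjects, testPP$masks,
                       nSlices = ns, nLevels = config$phantom@nLevels)
  }
  note("sweep", "kernel x dimension")
  fig1 <- kernelDimensionSweep(featurePairs, config$kernels,
                               trainSize = min(180L,
                                               max(config$trainingSizes)),
                               Cgrid = config$Cgrid,
                               gammaGrid = config$gammaGrid,
                               seed = deriveSeed(seed, 3L))
  # best condition -> size sweep at the best slice setting with rbf-style
  # final kernel: pick the condition with highest test accuracy
  bestRow <- fig1[order(-fig1$testCA, -fig1$testAUC), ][1, ]
  bestPair <- featurePairs[[as.character(bestRow$nSlices)]]
  note("sweep", "training sizes with ", config$repetitions, " repetitions")
  sweep <- trainingSizeSweep(bestPair$train, bestPair$test,
                             config$trainingSizes, config$repetitions,
                             kind = bestRow$kernel, Cgrid = config$Cgrid,
                             gammaGrid = config$gammaGrid,
                             seed = deriveSeed(seed, 4L))
  # final model at the largest size on the full training population
  note("classify", "final model on full training set")
  final <- trainEvaluate(bestPair$train, bestPair$test, bestRow$kernel,
                         config$Cgrid, config$gammaGrid,
                         deriveSeed(seed, 5L))
  truth <- bestPair$test@labels
  note("evaluate", "reader simulation + comparison statistics")
  reader1 <- simulateReaders(truth, 0.82, 0.76, deriveSeed(seed, 6L))
  reader2 <- simulateReaders(truth, 0.84, 0.80, deriveSeed(seed, 7L))
  r1lab <- binarizeScores(reader1)
  r2lab <- binarizeScores(reader2)
  table2 <- rbind(
    formatMetricsRow(final$test, "SVM"),
    formatMetricsRow(confusionMetrics(r1lab, truth), "Reader 1"),
    formatMetricsRow(confusionMetrics(r2lab, truth), "Reader 2"))
  comparison <- list(
    mcnemarR1 = mcnemarTest(final$testPred$label, r1lab, truth),
    mcnemarR2 = mcnemarTest(final$testPred$label, r2lab, truth),
    kappaR1 = cohenKappa(final$testPred$label, r1lab),
    kappaR2 = cohenKappa(final$testPred$label, r2lab),
    aucSvm = rocAuc(final$testPred$score, truth),
    aucR1 = rocAuc(reader1, truth),
    aucR2 = rocAuc(reader2, truth),
    deLongR1 = compareAuc(final$testPred$score, reader1, truth),
    deLongR2 = compareAuc(final$testPred$score, reader2, truth))
  note("learncurve", "inverse power law on mean accuracies")
  means <- sweep$summary[sweep$summary$metric == "CA" &
                           sweep$summary$stat == "mean", ]
  curve <- NULL
  if (nrow(means) >= 4L)
    curve <- tryCatch(fitInversePower(means$size, means$value),
                      error = function(e) NULL)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(fig1, file.path(outDir, "fig1_data.csv"),
                     row.names = FALSE)
    utils::write.csv(sweep$summary, file.path(outDir, "table1.csv"),
                     row.names = FALSE)
    utils::write.csv(sweep$records, file.path(outDir, "table1_records.csv"),
                     row.names = FALSE)
    utils::write.csv(table2, file.path(outDir, "table2.csv"),
                     row.names = FALSE)
    utils::write.csv(means[, c("size", "value")],
                     file.path(outDir, "fig3_points.csv"),
                     row.names = FALSE)
    writeLines(vapply(logLines, jsonlite::toJSON, character(1),
                      auto_unbox = TRUE),
               file.path(outDir, "run_log.json"))
  }
  invisible(list(fig1 = fig1, sizeSweep = sweep, final = final,
                 table2 = table2, comparison = comparison,
                 learningCurve = curve, readers = list(reader1, reader2),
                 featurePairs = featurePairs, config = config))
}
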