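test_that("reader score binarization maps 0-2 negative, 3-4 positive", {
  expect_identical(binarizeScores(c(0L, 1L, 2L, 3L, 4L)),
                   c(0L, 0L, 0L, 1L, 1L))
  expect_identical(binarizeScores(rep(0L, 5)), rep(0L, 5))
  expect_error(binarizeScores(c(1L, 5L)), "0..4")
})

test_that("confusion metrics satisfy the integer identity and Wilson properties", {
  set.seed(4)
  for (i in 1:20) {
    n <- sample(20:200, 1)
    truth <- rbinom(n, 1, 0.5)
    pred <- ifelse(runif(n) < 0.8, truth, 1 - truth)
    m <- confusionMetrics(pred, truth)
    expect_identical(unname(m$counts["TP"] + m$counts["TN"]),
                     as.integer(round(m$accuracy$estimate * m$n)))
    for (stat in list(m$accuracy, m$sensitivity, m$specificity)) {
      expect_lte(stat$ci["lower"], stat$estimate)
      expect_gte(stat$ci["upper"], stat$estimate)
    }
  }
  # Wilson width shrinks with n at fixed proportion
  w1 <- diff(wilsonCI(8, 10))
  w2 <- diff(wilsonCI(80, 100))
  expect_lt(w2, w1)
  # perfect prediction: upper bound reaches 1
  p <- confusionMetrics(rep(1, 10), rep(1, 10))
  expect_identical(unname(p$accuracy$estimate), 1)
  expect_identical(unname(p$accuracy$ci["upper"]), 1)
  expect_error(confusionMetrics(integer(0), integer(0)), "empty")
})

test_that("AUC equals the exhaustive pairwise probability", {
  expect_equal(rocAuc(c(0.9, 0.8, 0.4, 0.7, 0.3, 0.2),
                      c(1, 1, 1, 0, 0, 0))$auc, 8 / 9)
  # perfectly separated and fully tied cases
  expect_identical(rocAuc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_identical(rocAuc(rep(2, 6), c(0, 1, 0, 1, 0, 1))$auc, 0.5)
  set.seed(8)
  for (i in 1:20) {
    n <- sample(8:40, 1)
    truth <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- round(rnorm(n), 1) # coarse grid to force ties
    expect_equal(rocAuc(scores, truth)$auc, pairwiseAuc(scores, truth))
  }
  expect_error(rocAuc(1:4, rep(1, 4)), "both classes")
})

test_that("DeLong AUC machinery agrees with pROC", {
  skip_if_not_installed("pROC")
  set.seed(12)
  truth <- rbinom(80, 1, 0.5)
  sa <- rnorm(80) + truth
  sb <- rnorm(80) + 0.5 * truth
  r <- rocAuc(sa, truth)
  pr <- pROC::roc(truth, sa, quiet = TRUE, direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(pr)))
  ciP <- as.numeric(pROC::ci.auc(pr, method = "delong"))
  expect_equal(unname(r$ci), ciP[c(1, 3)], tolerance = 1e-6)
  cmp <- compareAuc(sa, sb, truth)
  prB <- pROC::roc(truth, sb, quiet = TRUE, direction = "<")
  pP <- pROC::roc.test(pr, prB, method = "delong")$p.value
  expect_equal(cmp$p, pP, tolerance = 1e-6)
})

test_that("AUC comparison is rank-invariant and null on identical scores", {
  set.seed(3)
  truth <- rbinom(40, 1, 0.5)
  s <- rnorm(40)
  expect_identical(compareAuc(s, s, truth)$p, 1)
  # monotone transform preserves the ROC exactly
  expect_identical(compareAuc(s, exp(s), truth)$p, 1)
  expect_error(compareAuc(s, s[-1], truth[-1]), "same subjects")
})

test_that("McNemar discordant-pair arithmetic matches binomial enumeration", {
  # b10 = 8, b01 = 2: exact p = 2 * P(X <= 2 | n = 10, 1/2) = 112/1024
  truth <- rep(1L, 30)
  predA <- rep(1L, 30)
  predB <- c(rep(0L, 8), rep(1L, 22))       # A correct, B wrong: 8
  predA[9:10] <- 0L; predB[9:10] <- 1L      # A wrong, B correct: 2
  r <- mcnemarTest(predA, predB, truth)
  expect_identical(c(r$b10, r$b01), c(8L, 2L))
  expect_equal(r$p, 112 / 1024)
  # identical predictions: no discordance
  expect_identical(mcnemarTest(predA, predA, truth)$p, 1)
  # symmetric discordance maximizes p at the given total
  sym <- mcnemarTest(c(rep(1L, 5), rep(0L, 5)), c(rep(0L, 5), rep(1L, 5)),
                     rep(1L, 10))
  expect_identical(sym$p, 1)
  # large discordance switches to the corrected chi-square
  pa <- c(rep(1L, 20), rep(0L, 10)); pb <- c(rep(0L, 20), rep(1L, 10))
  big <- mcnemarTest(pa, pb, rep(1L, 30))
  expect_match(big$method, "chi-square")
  expect_equal(big$p, pchisq((abs(20 - 10) - 1)^2 / 30, 1,
                             lower.tail = FALSE))
})

test_that("Cohen's kappa matches the closed form and its bands", {
  # agreement table (40, 10; 10, 40): po = 0.8, pe = 0.5, kappa = 0.6
  a <- c(rep(1L, 50), rep(0L, 50))
  b <- c(rep(1L, 40), rep(0L, 10), rep(1L, 10), rep(0L, 40))
  r <- cohenKappa(a, b)
  expect_equal(r$kappa, 0.6)
  expect_identical(r$band, "moderate")
  # self-agreement and label-swap invariance
  expect_identical(cohenKappa(a, a)$kappa, 1)
  expect_identical(cohenKappa(a, a)$band, "almost perfect")
  expect_equal(cohenKappa(1L - a, 1L - b)$kappa, r$kappa)
  # paper band example
  expect_identical(marrowtex:::kappaBand(0.45), "moderate")
  expect_identical(marrowtex:::kappaBand(0.15), "slight")
  # degenerate equal-constant raters
  d <- cohenKappa(rep(1L, 5), rep(1L, 5))
  expect_identical(d$kappa, 1)
  expect_true(d$degenerate)
})

test_that("metrics format as percentage rows with bracketed CIs", {
  m <- confusionMetrics(c(rep(1, 88), rep(0, 19)), rep(1, 107))
  row <- formatMetricsRow(m, "SVM")
  expect_match(row$CA, "^82.2 \\[73.9-88.3\\]$")
})
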