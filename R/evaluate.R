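#' Wilson score confidence interval for a binomial proportion
#'
#' @param k successes, `n` trials, `conf` confidence level.
#' @param n,conf see above.
#' @return numeric(2), lower and upper bound.
#' @export
wilsonCI <- function(k, n, conf = 0.95) {
  stopifnot(n > 0, k >= 0, k <= n)
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  ctr <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(lower = max(0, ctr - hw), upper = min(1, ctr + hw))
}

#' Binarize five-level reader confidence scores
#'
#' Ordinal confidence 0 = definitely absent .. 4 = definitely present;
#' 0--2 counts as negative, 3--4 as positive.
#'
#' @param scores integer vector in 0..4.
#' @return integer 0/1 labels.
#' @export
binarizeScores <- function(scores) {
  if (any(!scores %in% 0:4)) stop("reader scores must lie in 0..4")
  as.integer(scores >= 3)
}

#' Confusion-matrix diagnostic metrics with Wilson CIs
#'
#' Accuracy `(TP+TN)/n`, sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`,
#' each with a 95% Wilson score interval.
#'
#' @param pred,truth binary 0/1 vectors of equal length.
#' @param conf confidence level.
#' @return a `MetricsReport` list: `counts` (TP, FP, TN, FN), `accuracy`,
#'   `sensitivity`, `specificity` (each `list(estimate, ci)`), `n`.
#' @export
confusionMetrics <- function(pred, truth, conf = 0.95) {
  stopifnot(length(pred) == length(truth))
  if (length(pred) == 0L) stop("empty input")
  pred <- as.integer(pred); truth <- as.integer(truth)
  tp <- sum(pred == 1L & truth == 1L)
  tn <- sum(pred == 0L & truth == 0L)
  fp <- sum(pred == 1L & truth == 0L)
  fn <- sum(pred == 0L & truth == 1L)
  n <- length(pred)
  prop <- function(k, m) list(estimate = if (m > 0) k / m else NA_real_,
                              ci = if (m > 0) wilsonCI(k, m, conf) else
                                c(lower = NA_real_, upper = NA_real_))
  structure(list(counts = c(TP = tp, FP = fp, TN = tn, FN = fn),
                 accuracy = prop(tp + tn, n),
                 sensitivity = prop(tp, tp + fn),
                 specificity = prop(tn, tn + fp),
                 n = n),
            class = "MetricsReport")
}

# DeLong structural components: placement values of positive and negative
# scores (ties count 1/2)
delongPlacements <- function(scores, truth) {
  x <- scores[truth == 1L]  # diseased
  y <- scores[truth == 0L]  # controls
  m <- length(x); n <- length(y)
  if (m == 0L || n == 0L) stop("both classes must be present")
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  list(auc = mean(psi), v10 = rowMeans(psi), v01 = colMeans(psi),
       m = m, n = n)
}

#' ROC area under the curve with DeLong confidence interval
#'
#' AUC is the probability that a random diseased score exceeds a random
#' control score, ties counted one half (equivalently the trapezoidal area
#' under the empirical ROC). The CI uses the DeLong variance.
#'
#' @param scores real-valued classifier scores (higher = more diseased).
#' @param truth binary 0/1 vector.
#' @param conf confidence level.
#' @return list: `auc`, `var`, `ci` (Wald on the AUC scale, clipped to
#'   [0, 1]).
#' @export
rocAuc <- function(scores, truth, conf = 0.95) {
  pl <- delongPlacements(scores, as.integer(truth))
  v <- 0
  if (pl$m > 1L) v <- v + var(pl$v10) / pl$m
  if (pl$n > 1L) v <- v + var(pl$v01) / pl$n
  z <- qnorm(1 - (1 - conf) / 2)
  ci <- pl$auc + c(-1, 1) * z * sqrt(v)
  list(auc = pl$auc, var = v,
       ci = c(lower = max(0, ci[1]), upper = min(1, ci[2])))
}

#' Paired DeLong comparison of two correlated AUCs
#'
#' Both score sets must be measured on the same subjects (same truth).
#' Returns the two-sided p-value for equality of the AUCs. Identical (or
#' rank-identical) score sets give p = 1.
#'
#' @param scoresA,scoresB score vectors on the same subjects.
#' @param truth binary 0/1 vector.
#' @return list: `aucA`, `aucB`, `varDiff`, `z`, `p`.
#' @export
compareAuc <- function(scoresA, scoresB, truth) {
  if (length(scoresA) != length(scoresB) ||
      length(scoresA) != length(truth))
    stop("score sets must cover the same subjects")
  truth <- as.integer(truth)
  a <- delongPlacements(scoresA, truth)
  b <- delongPlacements(scoresB, truth)
  s10 <- cov(cbind(a$v10, b$v10))
  s01 <- cov(cbind(a$v01, b$v01))
  vd <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / a$m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / a$n
  dA <- a$auc - b$auc
  if (vd <= 0) {
    z <- if (dA == 0) 0 else Inf * sign(dA)
  } else z <- dA / sqrt(vd)
  p <- if (is.infinite(z)) 0 else 2 * pnorm(-abs(z))
  list(aucA = a$auc, aucB = b$auc, varDiff = vd, z = z, p = p)
}

#' McNemar test on paired classifications
#'
#' Builds the discordant counts against the truth (`b10`: A correct, B
#' wrong; `b01`: A wrong, B correct). Exact two-sided binomial test when
#' fewer than 25 discordant pairs, otherwise chi-square with continuity
#' correction.
#'
#' @param predA,predB binary predictions on the same subjects.
#' @param truth binary 0/1 vector.
#' @return list: `b10`, `b01`, `p`, `method`.
#' @export
mcnemarTest <- function(predA, predB, truth) {
  stopifnot(length(predA) == length(predB),
            length(predA) == length(truth))
  okA <- as.integer(predA) == as.integer(truth)
  okB <- as.integer(predB) == as.integer(truth)
  b10 <- sum(okA & !okB)
  b01 <- sum(!okA & okB)
  nd <- b10 + b01
  if (nd == 0L)
    return(list(b10 = 0L, b01 = 0L, p = 1, method = "exact"))
  if (nd < 25L) {
    p <- min(1, 2 * pbinom(min(b10, b01), nd, 0.5))
    method <- "exact"
  } else {
    stat <- (abs(b10 - b01) - 1)^2 / nd
    p <- pchisq(stat, df = 1, lower.tail = FALSE)
    method <- "chi-square (continuity corrected)"
  }
  list(b10 = b10, b01 = b01, p = p, method = method)
}

kappaBand <- function(kappa) {
  eps <- 1e-9 # cut-points compared at printed precision, not float noise
  if (kappa <= 0 + eps) "poor"
  else if (kappa <= 0.20 + eps) "slight"
  else if (kappa <= 0.40 + eps) "fair"
  else if (kappa <= 0.60 + eps) "moderate"
  else if (kappa <= 0.80 + eps) "substantial"
  else "almost perfect"
}

#' Cohen's kappa for two binary raters
#'
#' `kappa = (po - pe) / (1 - pe)` with expected agreement `pe` from the
#' marginal products. Interpretation bands: poor (<= 0), slight (0--0.2],
#' fair (0.2--0.4], moderate (0.4--0.6], substantial (0.6--0.8], almost
#' perfect (0.8--1]. When both raters are constant and identical (`pe = 1`)
#' kappa is defined as 1 by convention and flagged.
#'
#' @param labelsA,labelsB binary 0/1 vectors of equal length.
#' @return an `AgreementResult` list: `kappa`, `band`, `po`, `pe`,
#'   `degenerate`.
#' @export
cohenKappa <- function(labelsA, labelsB) {
  stopifnot(length(labelsA) == length(labelsB), length(labelsA) > 0L)
  a <- as.integer(labelsA); b <- as.integer(labelsB)
  stopifnot(all(a %in% 0:1), all(b %in% 0:1))
  n <- length(a)
  po <- mean(a == b)
  pe <- mean(a) * mean(b) + mean(1 - a) * mean(1 - b)
  if (pe >= 1) {
    return(list(kappa = 1, band = kappaBand(1), po = po, pe = pe,
                degenerate = TRUE))
  }
  k <- (po - pe) / (1 - pe)
  list(kappa = k, band = kappaBand(k), po = po, pe = pe, degenerate = FALSE)
}

#' Format a metrics report as a percentage table row
#'
#' @param report a `MetricsReport` from [confusionMetrics].
#' @param label row label.
#' @return one-row data.frame with `CA`, `SE`, `SP` formatted as
#'   "xx.x [lo-hi]".
#' @export
formatMetricsRow <- function(report, label = "SVM") {
  fmt <- function(m) sprintf("%.1f [%.1f-%.1f]", 100 * m$estimate,
                             100 * m$ci["lower"], 100 * m$ci["upper"])
  data.frame(model = label, CA = fmt(report$accuracy),
             SE = fmt(report$sensitivity), SP = fmt(report$specificity),
             stringsAsFactors = FALSE)
}
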