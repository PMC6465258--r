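#' Evaluate the inverse-power-law learning curve
#'
#' `y(x) = (1 - a) - b * x^c`. Undefined at `x = 0` when `c < 0`.
#'
#' @param fit a [LearningCurveFit-class] or a named numeric `c(a=, b=, c=)`.
#' @param x training-set sizes (> 0).
#' @return predicted performance at each `x`.
#' @export
evaluateCurve <- function(fit, x) {
  co <- if (is(fit, "LearningCurveFit")) fit@coefficients else fit
  stopifnot(all(c("a", "b", "c") %in% names(co)))
  if (any(x < 0)) stop("x must be >= 0")
  if (any(x == 0) && co["c"] < 0)
    stop("curve undefined at x = 0 for negative decay rate")
  unname((1 - co["a"]) - co["b"] * x^co["c"])
}

#' Weighted SSE and RMSE goodness of fit
#'
#' `SSE = sum(w * (y - yhat)^2)`; `RMSE = sqrt(SSE / (n - m))` with `m` the
#' number of fitted coefficients.
#'
#' @param y observed, `yhat` predicted, `w` weights, `m` coefficient count.
#' @param yhat,w,m see above.
#' @return list `sse`, `rmse`, `n`, `m`.
#' @export
goodnessOfFit <- function(y, yhat, w = rep(1, length(y)), m = 3L) {
  stopifnot(length(y) == length(yhat))
  n <- length(y)
  if (n <= m) stop("need more points than fitted coefficients")
  sse <- sum(w * (y - yhat)^2)
  list(sse = sse, rmse = sqrt(sse / (n - m)), n = n, m = m)
}

#' Fit the inverse power law by Levenberg--Marquardt least squares
#'
#' Weighted nonlinear least squares for `y = (1 - a) - b * x^c`
#' (Levenberg--Marquardt, via minpack.lm), initialized at
#' `a0 = 1 - max(y)`, `b0 = 1`, `c0 = -0.5`. Points at `x = 0` are excluded
#' from the fit with a message (the model is undefined there for `c < 0`);
#' at least 4 positive-size points are required so the residual degrees of
#' freedom are positive.
#'
#' @param x training-set sizes.
#' @param y observed performance (proportions in [0, 1]).
#' @param w weights (default 1).
#' @return a [LearningCurveFit-class] (slots include SSE, RMSE, covariance).
#' @export
fitInversePower <- function(x, y, w = rep(1, length(x))) {
  stopifnot(length(x) == length(y), length(x) == length(w), all(w > 0),
            all(y >= 0), all(y <= 1), all(x >= 0))
  if (any(x == 0)) {
    message("excluding ", sum(x == 0),
            " point(s) at x = 0 from the nonlinear fit")
    keep <- x > 0
    x <- x[keep]; y <- y[keep]; w <- w[keep]
  }
  if (length(x) <= 3L)
    stop("need at least 4 points with x > 0 (zero residual df otherwise)")
  df <- data.frame(x = x, y = y)
  start <- list(a = 1 - max(y), b = 1, c = -0.5)
  fit <- minpack.lm::nlsLM(
    y ~ (1 - a) - b * x^c, data = df, start = start, weights = w,
    control = minpack.lm::nls.lm.control(maxiter = 1024L, ftol = 1e-10,
                                         ptol = 1e-10))
  co <- coef(fit)
  yhat <- (1 - co["a"]) - co["b"] * x^co["c"]
  gof <- goodnessOfFit(y, yhat, w, m = 3L)
  covm <- tryCatch(unname(vcov(fit)),
                   error = function(e) matrix(NA_real_, 3, 3))
  mono <- unname(co["b"] > 0 && co["c"] < 0)
  if (!mono)
    warning("fitted curve is not monotone increasing (b > 0, c < 0 violated)")
  new("LearningCurveFit",
      coefficients = c(a = unname(co["a"]), b = unname(co["b"]),
                       c = unname(co["c"])),
      covariance = covm, sse = gof$sse, rmse = gof$rmse,
      sigma2 = gof$sse / (gof$n - gof$m),
      x = x, y = y, w = w, monotone = mono)
}

#' Training size required to reach a target performance
#'
#' Inverts the fitted curve: `x* = ((1 - a - target) / b)^(1/c)`, returned
#' as the smallest integer at or above `x*` (the next integer when `x*` is
#' itself integral, so the returned size strictly exceeds non-attained
#' real-valued solutions).
#'
#' @param fit a [LearningCurveFit-class] (requires `b > 0`, `c < 0`).
#' @param target desired performance, must lie below the asymptote `1 - a`.
#' @return integer training-set size.
#' @export
requiredSampleSize <- function(fit, target) {
  co <- if (is(fit, "LearningCurveFit")) fit@coefficients else fit
  a <- co["a"]; b <- co["b"]; cc <- co["c"]
  if (!(b > 0 && cc < 0))
    stop("inversion requires b > 0 and c < 0")
  if (target >= 1 - a)
    stop("target exceeds asymptote 1 - a = ", signif(1 - a, 6))
  xstar <- unname(((1 - a - target) / b)^(1 / cc))
  if (abs(xstar - round(xstar)) < 1e-8) as.integer(round(xstar)) + 1L
  else as.integer(ceiling(xstar))
}

#' Delta-method 95% prediction bounds for the fitted curve
#'
#' `yhat(x) +/- t_{n-m} * sqrt(g' Sigma g + s^2)` with `g` the gradient of
#' the curve in (a, b, c), `Sigma` the coefficient covariance and `s^2` the
#' residual variance.
#'
#' @param fit a [LearningCurveFit-class].
#' @param xGrid positive sizes to evaluate at.
#' @param level confidence level (default 0.95).
#' @return data.frame: `x`, `fit`, `lower`, `upper`.
#' @export
predictionBounds <- function(fit, xGrid, level = 0.95) {
  stopifnot(is(fit, "LearningCurveFit"), all(xGrid > 0))
  S <- fit@covariance
  if (any(!is.finite(S))) stop("singular or unavailable covariance")
  co <- fit@coefficients
  n <- length(fit@x)
  tq <- qt(1 - (1 - level) / 2, df = n - 3L)
  yhat <- evaluateCurve(fit, xGrid)
  hw <- vapply(seq_along(xGrid), function(i) {
    xx <- xGrid[i]
    g <- c(-1, -xx^co["c"], -co["b"] * xx^co["c"] * log(xx))
    tq * sqrt(max(0, drop(t(g) %*% S %*% g)) + fit@sigma2)
  }, numeric(1))
  data.frame(x = xGrid, fit = yhat, lower = yhat - hw, upper = yhat + hw)
}
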