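#' Construct an SVM kernel specification
#'
#' Kernels follow the libsvm forms: `poly3` is `(gamma*u'v + coef0)^3`,
#' `tanh` is `tanh(gamma*u'v + coef0)`, `rbf` is `exp(-gamma*||u - v||^2)`.
#'
#' @param kind `"poly3"`, `"tanh"` or `"rbf"`.
#' @param C soft-margin cost (> 0).
#' @param gamma kernel coefficient (> 0).
#' @param coef0 offset for poly3/tanh (default 0, the libsvm default).
#' @return a [KernelSpec-class].
#' @export
kernelSpec <- function(kind, C = 1, gamma = 1, coef0 = 0) {
  # initialize() rather than new(): a named `C` argument would partially
  # match new()'s `Class` formal
  spec <- initialize(new("KernelSpec"), kind = kind, C = C, gamma = gamma,
                     coef0 = coef0)
  validObject(spec)
  spec
}

#' Canonical grid-search ranges
#'
#' The libsvm practical-guide grids: `C = 2^(-5), 2^(-3), ..., 2^15` and
#' `gamma = 2^(-15), 2^(-13), ..., 2^3`.
#'
#' @return named list with `C` and `gamma` vectors.
#' @export
defaultGrids <- function() {
  list(C = 2^seq(-5, 15, by = 2), gamma = 2^seq(-15, 3, by = 2))
}

# stratified k-fold assignment, reproducible from seed
stratifiedFolds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  withSeed(seed, function() {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <<- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

svmFit <- function(x, y, spec) {
  kernel <- switch(spec@kind, poly3 = "polynomial", tanh = "sigmoid",
                   rbf = "radial")
  e1071::svm(x = x, y = factor(y, levels = c(0L, 1L)), scale = FALSE,
             kernel = kernel, degree = 3L, cost = spec@C,
             gamma = spec@gamma, coef0 = spec@coef0)
}

#' Grid search over (C, gamma) by stratified 5-fold cross-validation
#'
#' Every grid point is scored by stratified k-fold CV accuracy on the scaled
#' training matrix; ties are broken toward the smallest C, then the smallest
#' gamma. The fold split is reproducible from `seed`.
#'
#' @param fm a scaled [FeatureMatrix-class] with at least `folds` subjects
#'   per class.
#' @param kind kernel kind (see [kernelSpec]).
#' @param Cgrid,gammaGrid numeric grids (defaults: [defaultGrids]).
#' @param seed fold-assignment seed.
#' @param folds number of CV folds (default 5).
#' @param coef0 kernel offset.
#' @return list: `best` ([KernelSpec-class]), `cvAccuracy`, `grid`
#'   (data.frame of C, gamma, accuracy), `folds`, `seed`.
#' @export
gridSearchCV <- function(fm, kind, Cgrid = defaultGrids()$C,
                         gammaGrid = defaultGrids()$gamma, seed = 1L,
                         folds = 5L, coef0 = 0) {
  y <- fm@labels
  if (length(unique(y)) < 2L) stop("both classes must be present")
  stopifnot(length(Cgrid) >= 1L, length(gammaGrid) >= 1L)
  fold <- stratifiedFolds(y, folds, seed)
  x <- fm@x
  grid <- expand.grid(C = sort(Cgrid), gamma = sort(gammaGrid))
  grid <- grid[order(grid$C, grid$gamma), ]
  acc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    spec <- kernelSpec(kind, grid$C[g], grid$gamma[g], coef0)
    correct <- 0L
    for (f in seq_len(folds)) {
      tr <- fold != f; te <- fold == f
      if (!any(te)) next
      if (length(unique(y[tr])) < 2L) next
      m <- svmFit(x[tr, , drop = FALSE], y[tr], spec)
      p <- predict(m, x[te, , drop = FALSE])
      correct <- correct + sum(as.integer(as.character(p)) == y[te])
    }
    acc[g] <- correct / length(y)
  }
  best <- which.max(acc) # grid sorted by (C, gamma): first max = smallest tie
  list(best = kernelSpec(kind, grid$C[best], grid$gamma[best], coef0),
       cvAccuracy = acc[best],
       grid = cbind(grid, accuracy = acc),
       folds = folds, seed = seed)
}

#' Train a soft-margin C-SVM
#'
#' @param fm a scaled [FeatureMatrix-class] with both classes present.
#' @param spec a [KernelSpec-class].
#' @return an `SvmModel` list: the fitted libsvm model, the spec, the number
#'   of support vectors and the feature dimension.
#' @export
trainSvm <- function(fm, spec) {
  if (length(unique(fm@labels)) < 2L)
    stop("degenerate single-class training input")
  m <- svmFit(fm@x, fm@labels, spec)
  structure(list(model = m, spec = spec, nSV = sum(m$nSV),
                 dimension = ncol(fm@x)),
            class = "SvmModel")
}

#' Predict with a trained SVM
#'
#' Scores are signed decision values oriented so positive means class 1
#' (diseased); predicted label is `score > threshold` with the default
#' threshold 0.
#'
#' @param model an `SvmModel` from [trainSvm].
#' @param fm a [FeatureMatrix-class] scaled with the training scaler.
#' @param threshold decision threshold on the score (default 0).
#' @return a `PredictionSet` data.frame: `subjectId`, `score`, `label`.
#' @export
predictSvm <- function(model, fm, threshold = 0) {
  if (ncol(fm@x) != model$dimension)
    stop("feature dimension mismatch: ", ncol(fm@x), " != ",
         model$dimension)
  p <- predict(model$model, fm@x, decision.values = TRUE)
  dv <- attr(p, "decision.values")
  score <- dv[, 1]
  # libsvm orients decision values toward the first class in the colname
  if (grepl("^0/", colnames(dv)[1])) score <- -score
  data.frame(subjectId = fm@subjectIds,
             score = as.numeric(score),
             label = as.integer(score > threshold),
             stringsAsFactors = FALSE)
}
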