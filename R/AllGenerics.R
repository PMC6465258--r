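#' Accessors for marrowtex S4 objects
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param object a marrowtex S4 object.
#' @return the slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("voxels", function(object) standardGeneric("voxels"))

#' @rdname accessors
#' @export
setGeneric("anatomyLabels", function(object) standardGeneric("anatomyLabels"))

#' @rdname accessors
#' @export
setGeneric("diseaseStatus", function(object) standardGeneric("diseaseStatus"))

#' @rdname accessors
#' @export
setGeneric("confounds", function(object) standardGeneric("confounds"))

#' @rdname accessors
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))

#' @rdname accessors
#' @export
setGeneric("maskArray", function(object) standardGeneric("maskArray"))

#' @rdname accessors
#' @export
setGeneric("featureValues", function(object) standardGeneric("featureValues"))

#' @rdname accessors
#' @export
setGeneric("featureLabels", function(object) standardGeneric("featureLabels"))

#' @rdname accessors
#' @export
setGeneric("isScaled", function(object) standardGeneric("isScaled"))

#' @rdname accessors
#' @export
setMethod("voxels", "SpineSubject", function(object) object@voxels)

#' @rdname accessors
#' @export
setMethod("anatomyLabels", "SpineSubject", function(object) object@labels)

#' @rdname accessors
#' @export
setMethod("diseaseStatus", "SpineSubject", function(object) object@diseaseStatus)

#' @rdname accessors
#' @export
setMethod("confounds", "SpineSubject", function(object) object@confounds)

#' @rdname accessors
#' @export
setMethod("subjectId", "SpineSubject", function(object) object@subjectId)

#' @rdname accessors
#' @export
setMethod("maskArray", "MarrowMask", function(object) object@mask)

#' @rdname accessors
#' @export
setMethod("featureValues", "FeatureMatrix", function(object) object@x)

#' @rdname accessors
#' @export
setMethod("featureLabels", "FeatureMatrix", function(object) object@labels)

#' @rdname accessors
#' @export
setMethod("isScaled", "FeatureMatrix", function(object) object@scaled)

#' @rdname accessors
#' @export
setMethod("coef", "LearningCurveFit", function(object) object@coefficients)

setMethod("show", "PhantomConfig", function(object) {
  cat("PhantomConfig:", paste(object@imageShape, collapse = "x"),
      "voxels,", object@nLevels, "vertebral levels\n")
  cat("  marrow mean (normal/diseased):", object@marrowMeanNormal, "/",
      object@marrowMeanDiseased, "; texture SD:",
      object@marrowTextureSdNormal, "/", object@marrowTextureSdDiseased, "\n")
  cat("  disk nucleus/annulus:", object@diskNucleusMean, "/",
      object@annulusMean, "; noise SD:", object@noiseSd, "\n")
})

setMethod("show", "SpineSubject", function(object) {
  cat("SpineSubject", object@subjectId, "(",
      if (object@diseaseStatus == 1L) "diseased" else "control", ")\n")
  cat("  volume:", paste(dim(object@voxels), collapse = "x"),
      "; marrow voxels:",
      sum(object@labels >= 1L & object@labels <= 100L), "\n")
  if (length(object@confounds))
    cat("  confounds:", paste(object@confounds, collapse = ", "), "\n")
})

setMethod("show", "MarrowMask", function(object) {
  cat("MarrowMask:", sum(object@mask), "foreground voxels;",
      object@iterations, "iterations;",
      if (object@converged) "converged" else "NOT converged", "\n")
})

setMethod("show", "WindowSpec", function(object) {
  cat("WindowSpec:", object@height, "x", object@width, "window,",
      object@nLevels, "levels x", object@nSlices, "slice(s); dimension",
      object@nLevels * object@height * object@width * object@nSlices, "\n")
})

setMethod("show", "FeatureMatrix", function(object) {
  cat("FeatureMatrix:", nrow(object@x), "subjects x", ncol(object@x),
      "pixel features;", if (object@scaled) "scaled [0,1]" else "unscaled",
      "\n")
})

setMethod("show", "KernelSpec", function(object) {
  cat("KernelSpec:", object@kind, "C =", object@C, "gamma =", object@gamma,
      "coef0 =", object@coef0, "\n")
})

setMethod("show", "LearningCurveFit", function(object) {
  co <- object@coefficients
  cat(sprintf(
    "LearningCurveFit: y = (1 - %.4g) - %.4g * x^(%.4g)\n",
    co["a"], co["b"], co["c"]))
  cat(sprintf("  SSE = %.4g, RMSE = %.4g on %d points%s\n", object@sse,
              object@rmse, length(object@x),
              if (object@monotone) "" else "  [warning: not monotone]"))
})
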