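#' @import methods
NULL

#' Configuration of the synthetic spine phantom
#'
#' Parameters of the stylized sagittal lumbar-spine phantom used to generate
#' cohorts with known disease labels. Vertebral marrow is a spatially
#' correlated Gaussian random field whose mean and heterogeneity depend on
#' disease status; intervertebral disks carry a bright nucleus pulposus and a
#' darker annulus fibrosus (the first and last fifths of each disk's
#' anterior--posterior extent); scanner ("vendor") heterogeneity is modelled
#' as a per-subject global affine intensity map plus i.i.d. Gaussian noise.
#'
#' @slot imageShape integer(3), voxel counts as (slices, rows, cols). Rows
#'   increase superior to inferior, columns anterior to posterior.
#' @slot nLevels integer, number of vertebral bodies (level 1 = S1, most
#'   caudal).
#' @slot marrowMeanNormal,marrowMeanDiseased numeric, marrow mean intensity
#'   (arbitrary units) for control and diseased subjects.
#' @slot marrowTextureSdNormal,marrowTextureSdDiseased numeric, within-marrow
#'   heterogeneity SD.
#' @slot textureCorrLen numeric, spatial correlation length (voxels) of the
#'   marrow random field (Gaussian smoothing scale; 0 = white noise).
#' @slot diskNucleusMean,annulusMean numeric, disk compartment intensities.
#' @slot vendorOffsetRange,vendorScaleRange numeric(2), uniform ranges of the
#'   per-subject global intensity offset and scale.
#' @slot noiseSd numeric, additive acquisition noise SD.
#' @slot lesionProbs named numeric(3), probabilities of fracture-like,
#'   hemangioma-like and Modic-like focal insertions per subject.
#' @slot seed integer, default RNG seed used when none is supplied.
#' @export
setClass("PhantomConfig", representation(
  imageShape = "integer",
  nLevels = "integer",
  marrowMeanNormal = "numeric",
  marrowMeanDiseased = "numeric",
  marrowTextureSdNormal = "numeric",
  marrowTextureSdDiseased = "numeric",
  textureCorrLen = "numeric",
  diskNucleusMean = "numeric",
  annulusMean = "numeric",
  vendorOffsetRange = "numeric",
  vendorScaleRange = "numeric",
  noiseSd = "numeric",
  lesionProbs = "numeric",
  seed = "integer"
))

setValidity("PhantomConfig", function(object) {
  msg <- character()
  if (length(object@imageShape) != 3L || any(object@imageShape < 1L))
    msg <- c(msg, "imageShape must be three positive voxel counts")
  if (object@nLevels < 1L)
    msg <- c(msg, "nLevels must be >= 1")
  sds <- c(object@marrowTextureSdNormal, object@marrowTextureSdDiseased,
           object@noiseSd)
  if (any(!is.finite(sds)) || any(sds < 0))
    msg <- c(msg, "all SDs must be finite and >= 0")
  if (object@textureCorrLen < 0)
    msg <- c(msg, "textureCorrLen must be >= 0")
  if (length(object@lesionProbs) != 3L ||
      any(object@lesionProbs < 0) || any(object@lesionProbs > 1))
    msg <- c(msg, "lesionProbs must be three probabilities in [0,1]")
  if (length(object@vendorOffsetRange) != 2L ||
      diff(object@vendorOffsetRange) < 0)
    msg <- c(msg, "vendorOffsetRange must be an increasing pair")
  if (length(object@vendorScaleRange) != 2L ||
      diff(object@vendorScaleRange) < 0 || any(object@vendorScaleRange <= 0))
    msg <- c(msg, "vendorScaleRange must be a positive increasing pair")
  if (length(msg)) msg else TRUE
})

#' A synthetic spine-MRI subject
#'
#' Holds the intensity volume, the co-registered anatomical label volume,
#' per-disk degeneration flags and ground-truth disease status for one
#' subject. Label codes: 0 background, `1..nLevels` vertebral body marrow
#' (1 = S1), `101..` intervertebral disks (disk `i` sits between bodies `i`
#' and `i+1`), 200 other tissue.
#'
#' @slot voxels 3D numeric array (slice, row, col), arbitrary intensity units.
#' @slot labels 3D integer array, same shape as `voxels`.
#' @slot spacing numeric(3), voxel size in mm per axis.
#' @slot diskDegenerated logical, one flag per disk (TRUE = degenerated).
#' @slot diseaseStatus integer, 0 control / 1 diseased.
#' @slot confounds character, inserted focal lesion types.
#' @slot subjectId character scalar.
#' @export
setClass("SpineSubject", representation(
  voxels = "array",
  labels = "array",
  spacing = "numeric",
  diskDegenerated = "logical",
  diseaseStatus = "integer",
  confounds = "character",
  subjectId = "character"
))

setValidity("SpineSubject", function(object) {
  msg <- character()
  if (!identical(dim(object@voxels), dim(object@labels)))
    msg <- c(msg, "voxels and labels must have identical shape")
  if (any(!is.finite(object@voxels)))
    msg <- c(msg, "voxel intensities must be finite")
  if (!object@diseaseStatus %in% c(0L, 1L))
    msg <- c(msg, "diseaseStatus must be 0 or 1")
  lab <- unique(as.integer(object@labels))
  nl <- sum(lab >= 1L & lab <= 100L)
  ok <- lab == 0L | (lab >= 1L & lab <= 100L) |
    (lab >= 101L & lab < 200L) | lab == 200L
  if (!all(ok))
    msg <- c(msg, "labels contain codes outside the declared code set")
  if (nl < 1L)
    msg <- c(msg, "at least one vertebral level must be present")
  if (length(msg)) msg else TRUE
})

#' GrowCut segmentation result
#'
#' @slot mask 3D logical array, TRUE where the foreground (marrow) label won.
#' @slot iterations integer, synchronous sweeps executed before fixpoint (or
#'   the iteration cap).
#' @slot converged logical, TRUE if no label changed on the final sweep.
#' @export
setClass("MarrowMask", representation(
  mask = "array",
  iterations = "integer",
  converged = "logical"
))

#' Rectangular feature-window geometry
#'
#' Population-minimal window covering the smallest vertebral marrow across a
#' cohort. One window per vertebral level per slice; windows are centred on
#' each level's in-slice marrow centroid and read whole (unmasked) pixel
#' blocks from the disk-normalized volume.
#'
#' @slot height,width integer, window extent in voxels (rows x cols).
#' @slot nLevels integer, number of vertebral levels windowed (S1 upward).
#' @slot nSlices integer, consecutive sagittal slices (1, 3 or 9), centred on
#'   the mid-sagittal slice.
#' @slot cohortFingerprint character, identifier of the cohort the window was
#'   fitted on.
#' @export
setClass("WindowSpec", representation(
  height = "integer",
  width = "integer",
  nLevels = "integer",
  nSlices = "integer",
  cohortFingerprint = "character"
))

setValidity("WindowSpec", function(object) {
  msg <- character()
  if (object@height < 1L || object@width < 1L)
    msg <- c(msg, "height and width must be >= 1")
  if (object@nSlices %% 2L != 1L)
    msg <- c(msg, "nSlices must be odd")
  if (length(msg)) msg else TRUE
})

#' Subjects-by-pixels feature matrix
#'
#' Rows are subjects, columns raw-pixel features in level-major then
#' slice-major order. When scaled, per-column min/max fitted on a training
#' matrix are stored so the identical affine map can be applied to test data
#' (out-of-range values are preserved, not clipped).
#'
#' @slot x numeric matrix, subjects x features.
#' @slot labels integer, 0/1 ground truth per row.
#' @slot subjectIds character, row identifiers.
#' @slot scaled logical.
#' @slot colMin,colMax numeric, per-column scaling parameters (length 0 when
#'   unscaled).
#' @export
setClass("FeatureMatrix", representation(
  x = "matrix",
  labels = "integer",
  subjectIds = "character",
  scaled = "logical",
  colMin = "numeric",
  colMax = "numeric"
))

setValidity("FeatureMatrix", function(object) {
  msg <- character()
  if (nrow(object@x) != length(object@labels))
    msg <- c(msg, "one label per row required")
  if (length(object@labels) && !all(object@labels %in% c(0L, 1L)))
    msg <- c(msg, "labels must be 0/1")
  if (object@scaled && length(object@colMin) != ncol(object@x))
    msg <- c(msg, "scaled matrix must carry per-column parameters")
  if (length(msg)) msg else TRUE
})

#' SVM kernel configuration
#'
#' @slot kind character, one of `"poly3"` (3rd-order polynomial), `"tanh"`
#'   (tangent hyperbolic / sigmoid) or `"rbf"` (radial basis function).
#' @slot C numeric, soft-margin cost, > 0.
#' @slot gamma numeric, kernel coefficient, > 0.
#' @slot coef0 numeric, offset term for poly3/tanh (default 0).
#' @export
setClass("KernelSpec", representation(
  kind = "character",
  C = "numeric",
  gamma = "numeric",
  coef0 = "numeric"
), prototype(kind = "rbf", C = 1, gamma = 1, coef0 = 0))

setValidity("KernelSpec", function(object) {
  msg <- character()
  if (!object@kind %in% c("poly3", "tanh", "rbf"))
    msg <- c(msg, "kind must be one of poly3, tanh, rbf")
  if (object@C <= 0) msg <- c(msg, "C must be > 0")
  if (object@gamma <= 0) msg <- c(msg, "gamma must be > 0")
  if (length(msg)) msg else TRUE
})

#' Fitted inverse-power-law learning curve
#'
#' Model `y(x) = (1 - a) - b * x^c` for classifier performance `y` as a
#' function of training-set size `x`; `a` is the minimum achievable error,
#' `b` the learning rate and `c` the decay rate. A sensible learning curve
#' has `b > 0` and `c < 0` (monotone increasing, asymptote `1 - a`).
#'
#' @slot coefficients named numeric(3): a, b, c.
#' @slot covariance 3x3 numeric matrix, covariance of (a, b, c).
#' @slot sse,rmse numeric, weighted sum of squared errors and
#'   `sqrt(SSE / (n - m))` with m = 3 fitted coefficients.
#' @slot sigma2 numeric, residual variance `SSE / (n - m)`.
#' @slot x,y,w numeric, the points the curve was fitted on.
#' @slot monotone logical, TRUE when b > 0 and c < 0.
#' @export
setClass("LearningCurveFit", representation(
  coefficients = "numeric",
  covariance = "matrix",
  sse = "numeric",
  rmse = "numeric",
  sigma2 = "numeric",
  x = "numeric",
  y = "numeric",
  w = "numeric",
  monotone = "logical"
))
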