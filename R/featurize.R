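#' Construct a window specification directly
#'
#' @param height,width window extent in voxels.
#' @param nLevels vertebral levels windowed (default 6, S1 to L1).
#' @param nSlices consecutive sagittal slices (1, 3 or 9).
#' @param cohortFingerprint identifier of the cohort the window was fitted
#'   on (free-form).
#' @return a [WindowSpec-class].
#' @export
windowSpec <- function(height, width, nLevels = 6L, nSlices = 1L,
                       cohortFingerprint = "manual") {
  new("WindowSpec", height = as.integer(height), width = as.integer(width),
      nLevels = as.integer(nLevels), nSlices = as.integer(nSlices),
      cohortFingerprint = cohortFingerprint)
}

# per-level mask on the mid-sagittal slice: segmentation mask restricted to
# the level's anatomical label (fallback to the label alone if the
# intersection is empty)
levelSliceMask <- function(subject, mask, level, slice) {
  lab <- subject@labels[slice, , ] == level
  m <- lab & mask[slice, , ]
  if (!any(m)) m <- lab
  m
}

#' Population-minimal rectangular window
#'
#' Scans every subject and vertebral level on the mid-sagittal slice and
#' returns the window just large enough to cover the smallest segmented
#' marrow bounding box in the cohort (height and width minimized
#' independently).
#'
#' @param subjects list of [SpineSubject-class].
#' @param masks list of [MarrowMask-class] (same order).
#' @param nLevels levels expected per subject.
#' @param nSlices slice setting recorded in the spec.
#' @return a [WindowSpec-class].
#' @export
computeMinWindow <- function(subjects, masks, nLevels = 6L, nSlices = 1L) {
  stopifnot(length(subjects) == length(masks), length(subjects) >= 1L)
  hmin <- wmin <- Inf
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    mk <- maskArray(masks[[i]])
    mid <- ceiling(dim(s@voxels)[1] / 2)
    for (lev in seq_len(nLevels)) {
      m <- s@labels[mid, , ] == lev & mk[mid, , ]
      if (!any(m)) m <- s@labels[mid, , ] == lev
      if (!any(m))
        stop("empty level mask: subject ", s@subjectId, ", level ", lev)
      rows <- range(which(apply(m, 1, any)))
      cols <- range(which(apply(m, 2, any)))
      hmin <- min(hmin, diff(rows) + 1L)
      wmin <- min(wmin, diff(cols) + 1L)
    }
  }
  fp <- sprintf("cohort-n%d-min%dx%d", length(subjects), hmin, wmin)
  windowSpec(hmin, wmin, nLevels, nSlices, fp)
}

# centred integer window range of length `len` around centre `ctr`, clamped
# inside [1, n]; errors if len > n
windowRange <- function(ctr, len, n, what) {
  if (len > n) stop("window ", what, " (", len, ") exceeds image extent (",
                    n, ")")
  lo <- round(ctr) - floor((len - 1) / 2)
  lo <- max(1L, min(lo, n - len + 1L))
  seq.int(lo, lo + len - 1L)
}

#' Extract the raw-pixel feature vector of one subject
#'
#' For each vertebral level (1..nLevels) a `height x width` window is
#' centred on the level's marrow centroid of the mid-sagittal slice; the
#' same in-plane window is read from `nSlices` consecutive slices centred on
#' the mid-sagittal slice (clamped to the volume with a warning if the stack
#' overflows). All window pixels are read from the disk-normalized volume,
#' masked or not, flattened row-major, and concatenated level-major then
#' slice-major. Dimension is `nLevels * height * width * nSlices`.
#'
#' @param subject a [SpineSubject-class] (already disk-normalized).
#' @param mask a [MarrowMask-class] for the subject.
#' @param spec a [WindowSpec-class].
#' @param volume intensity array to read from (defaults to the subject's).
#' @return numeric feature vector with attributes `subjectId` and `ordering`.
#' @export
extractFeatureVector <- function(subject, mask, spec,
                                 volume = voxels(subject)) {
  dm <- dim(volume)
  S <- dm[1]
  if (spec@nSlices > S)
    stop("nSlices (", spec@nSlices, ") exceeds available slices (", S, ")")
  mid <- ceiling(S / 2)
  half <- (spec@nSlices - 1L) / 2L
  s0 <- mid - half
  if (s0 < 1L || s0 + spec@nSlices - 1L > S) {
    s0 <- max(1L, min(s0, S - spec@nSlices + 1L))
    warning("slice stack clamped to volume edge")
  }
  slices <- seq.int(s0, s0 + spec@nSlices - 1L)
  mk <- maskArray(mask)
  out <- vector("list", spec@nLevels * spec@nSlices)
  k <- 0L
  for (lev in seq_len(spec@nLevels)) {
    m <- levelSliceMask(subject, mk, lev, mid)
    if (!any(m))
      stop("empty level mask: subject ", subject@subjectId, ", level ", lev)
    idx <- which(m, arr.ind = TRUE)
    rows <- windowRange(mean(idx[, 1]), spec@height, dm[2], "height")
    cols <- windowRange(mean(idx[, 2]), spec@width, dm[3], "width")
    for (s in slices) {
      win <- volume[s, rows, cols]
      k <- k + 1L
      out[[k]] <- as.vector(t(win)) # row-major flattening
    }
  }
  v <- unlist(out, use.names = FALSE)
  stopifnot(length(v) ==
              spec@nLevels * spec@height * spec@width * spec@nSlices)
  attr(v, "subjectId") <- subject@subjectId
  attr(v, "ordering") <- "level-major,slice-major,row-major"
  v
}

#' Assemble feature vectors into a matrix
#'
#' @param vectors list of equal-length feature vectors.
#' @param labels 0/1 ground truth, one per vector.
#' @param subjectIds optional row identifiers (taken from vector attributes
#'   when absent).
#' @return an unscaled [FeatureMatrix-class]; row order = input order.
#' @export
assembleMatrix <- function(vectors, labels, subjectIds = NULL) {
  stopifnot(length(vectors) == length(labels))
  if (is.null(subjectIds))
    subjectIds <- vapply(seq_along(vectors), function(i)
      attr(vectors[[i]], "subjectId") %||% sprintf("row-%d", i), character(1))
  if (length(vectors) == 0L)
    return(new("FeatureMatrix", x = matrix(numeric(), 0, 0),
               labels = integer(), subjectIds = character(),
               scaled = FALSE, colMin = numeric(), colMax = numeric()))
  d <- length(vectors[[1]])
  for (i in seq_along(vectors))
    if (length(vectors[[i]]) != d)
      stop("dimension mismatch for subject ", subjectIds[i], ": ",
           length(vectors[[i]]), " != ", d)
  x <- do.call(rbind, lapply(vectors, as.numeric))
  new("FeatureMatrix", x = x, labels = as.integer(labels),
      subjectIds = subjectIds, scaled = FALSE,
      colMin = numeric(), colMax = numeric())
}

#' Min--max scale feature matrices to [0, 1]
#'
#' Per-column `(v - min) / (max - min)` with min/max fitted on the training
#' matrix only and reused for the other matrices (standard leakage-free
#' protocol). Constant training columns map to 0 everywhere; out-of-range
#' test values are preserved, not clipped.
#'
#' @param train an unscaled training [FeatureMatrix-class] (nonempty).
#' @param others list of further matrices to scale with the training
#'   parameters.
#' @return list with `train` and `others`, all scaled.
#' @export
minmaxScale <- function(train, others = list()) {
  stopifnot(nrow(train@x) > 0L)
  mn <- apply(train@x, 2, min)
  mx <- apply(train@x, 2, max)
  rng <- mx - mn
  constant <- rng == 0
  applyScale <- function(fm) {
    x <- sweep(fm@x, 2, mn, "-")
    x <- sweep(x, 2, ifelse(constant, 1, rng), "/")
    if (any(constant)) x[, constant] <- 0
    initialize(fm, x = x, scaled = TRUE, colMin = mn, colMax = mx)
  }
  list(train = applyScale(train), others = lapply(others, applyScale))
}
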