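#' Select the reference intervertebral disk
#'
#' The intensity reference for normalization is the annulus fibrosus of a
#' non-degenerated disk; when several qualify the most cranial one is used
#' (largest disk index, since disk `i` lies between bodies `i` and `i+1` and
#' level numbering runs caudal to cranial).
#'
#' @param subject a [SpineSubject-class].
#' @return a `DiskROI` list: `diskLevel`, logical `mask`, `apAxis` (= 3, the
#'   column axis).
#' @export
selectReferenceDisk <- function(subject) {
  flags <- subject@diskDegenerated
  codes <- sort(unique(subject@labels[subject@labels >= 101L &
                                        subject@labels < 200L]))
  if (!length(codes)) stop("no reference disk: subject has no disks")
  lvl <- codes - 100L
  ok <- lvl[!flags[lvl]]
  if (!length(ok)) stop("no reference disk: all disks degenerated")
  pick <- max(ok)
  structure(list(diskLevel = pick,
                 mask = subject@labels == (100L + pick),
                 apAxis = 3L),
            class = "DiskROI")
}

#' Split a disk into five anterior--posterior regions
#'
#' Disk voxels are partitioned into five bins of equal width along the
#' anterior--posterior extent; bins 1 and 5 form the annulus fibrosus, the
#' middle three the nucleus. Bins are disjoint and cover the disk exactly.
#'
#' @param roi a `DiskROI` from [selectReferenceDisk].
#' @return list with `bins` (integer array, 0 outside the disk, 1..5 inside)
#'   and `annulus` (logical array).
#' @export
splitDiskRegions <- function(roi) {
  m <- roi$mask
  if (!any(m)) stop("empty disk ROI")
  ax <- roi$apAxis
  pos <- which(m, arr.ind = TRUE)[, ax]
  lo <- min(pos); hi <- max(pos)
  extent <- hi - lo + 1L
  if (extent < 5L) stop("disk too small to split: extent ", extent, " < 5")
  bins <- array(0L, dim = dim(m))
  binOf <- pmin(4L, as.integer(floor((pos - lo) / extent * 5))) + 1L
  # which() and which(arr.ind = TRUE) enumerate voxels in the same order
  bins[which(m)] <- binOf
  annulus <- m & (bins == 1L | bins == 5L)
  list(bins = bins, annulus = annulus)
}

#' Normalize a volume by its reference annulus fibrosus
#'
#' Subtracts the scalar mean intensity of the annulus voxels from every voxel
#' of the volume, making the output invariant to global intensity offsets;
#' the annulus mean of the output is zero to floating tolerance. Applying it
#' twice equals applying it once.
#'
#' @param volume 3D numeric array (e.g. `voxels(subject)`).
#' @param roi a `DiskROI`; its annulus is taken via [splitDiskRegions].
#' @return the normalized 3D array.
#' @export
normalizeByDisk <- function(volume, roi) {
  ann <- splitDiskRegions(roi)$annulus
  if (!any(ann)) stop("empty annulus")
  volume - mean(volume[ann])
}

#' Disk-normalize a subject in place
#'
#' Convenience wrapper: reference disk selection + annulus normalization.
#'
#' @param subject a [SpineSubject-class].
#' @return the subject with normalized `voxels`.
#' @export
normalizeSubject <- function(subject) {
  roi <- selectReferenceDisk(subject)
  initialize(subject, voxels = normalizeByDisk(subject@voxels, roi))
}

#' Automatic GrowCut seeding from anatomical labels
#'
#' Foreground seeds are the morphological erosion of each vertebral marrow
#' label; background seeds the erosion of the non-marrow region (background,
#' other tissue and disks together, since the segmentation target is the
#' marrow alone).
#'
#' @param subject a [SpineSubject-class].
#' @param erosionRadius Chebyshev erosion radius in voxels; 0 keeps the full
#'   labels.
#' @return a `SeedSet` list with integer array `label` (0 none, 1 foreground,
#'   2 background) and the radius used.
#' @export
autoSeeds <- function(subject, erosionRadius = 2L) {
  lab <- subject@labels
  marrow <- lab >= 1L & lab <= 100L
  levs <- sort(unique(lab[marrow]))
  fg <- array(FALSE, dim(lab))
  for (lv in levs) {
    e <- erodeMask(lab == lv, erosionRadius)
    if (!any(e))
      stop("vertebral level ", lv, " vanishes under erosion radius ",
           erosionRadius)
    fg <- fg | e
  }
  bg <- erodeMask(!marrow, erosionRadius)
  if (!any(bg)) stop("background region vanishes under erosion")
  seeds <- array(0L, dim(lab))
  seeds[bg] <- 2L
  seeds[fg] <- 1L
  structure(list(label = seeds, erosionRadius = as.integer(erosionRadius)),
            class = "SeedSet")
}
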