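#' Create a phantom configuration
#'
#' Defaults describe the study conditions the pipeline is exercised under:
#' six vertebral bodies (S1 to L1), nine sagittal slices so the largest
#' feature setting (9 consecutive slices) is exercisable, bright fatty marrow
#' relative to the disk nucleus in controls, and diffusely lowered mean with
#' raised heterogeneity in diseased marrow. Intensities are arbitrary T1-like
#' units.
#'
#' @param imageShape integer(3) voxel counts (slices, rows, cols).
#' @param nLevels number of vertebral bodies (1 = S1, most caudal).
#' @param marrowMeanNormal,marrowMeanDiseased marrow mean intensities.
#' @param marrowTextureSdNormal,marrowTextureSdDiseased marrow heterogeneity
#'   SDs.
#' @param textureCorrLen correlation length (voxels) of the marrow field.
#' @param diskNucleusMean,annulusMean disk compartment intensities.
#' @param vendorOffsetRange,vendorScaleRange uniform ranges of the per-subject
#'   global affine intensity perturbation.
#' @param noiseSd additive Gaussian acquisition-noise SD.
#' @param lesionProbs named probabilities for `fracture`, `hemangioma`,
#'   `modic` focal insertions.
#' @param seed default RNG seed.
#' @return a validated [PhantomConfig-class] object.
#' @examples
#' cfg <- phantomConfig(imageShape = c(3L, 60L, 48L), noiseSd = 0)
#' subj <- generateSubject(cfg, diseaseStatus = 0L, seed = 1L)
#' @export
phantomConfig <- function(imageShape = c(9L, 256L, 192L),
                          nLevels = 6L,
                          marrowMeanNormal = 150,
                          marrowMeanDiseased = 110,
                          marrowTextureSdNormal = 8,
                          marrowTextureSdDiseased = 16,
                          textureCorrLen = 2,
                          diskNucleusMean = 120,
                          annulusMean = 60,
                          vendorOffsetRange = c(-20, 20),
                          vendorScaleRange = c(0.9, 1.1),
                          noiseSd = 5,
                          lesionProbs = c(fracture = 0, hemangioma = 0,
                                          modic = 0),
                          seed = 1L) {
  new("PhantomConfig",
      imageShape = as.integer(imageShape),
      nLevels = as.integer(nLevels),
      marrowMeanNormal = marrowMeanNormal,
      marrowMeanDiseased = marrowMeanDiseased,
      marrowTextureSdNormal = marrowTextureSdNormal,
      marrowTextureSdDiseased = marrowTextureSdDiseased,
      textureCorrLen = textureCorrLen,
      diskNucleusMean = diskNucleusMean,
      annulusMean = annulusMean,
      vendorOffsetRange = vendorOffsetRange,
      vendorScaleRange = vendorScaleRange,
      noiseSd = noiseSd,
      lesionProbs = lesionProbs,
      seed = as.integer(seed))
}

# Deterministic stylized anatomy for a config: rectangular vertebral bodies
# stacked superior->inferior with lens-shaped disks between them, extruded
# across all slices; a posterior soft-tissue band (code 200). Level 1 = S1
# occupies the lowest rows (rows increase superior->inferior).
buildAnatomy <- function(config) {
  shp <- config@imageShape
  S <- shp[1]; R <- shp[2]; Cc <- shp[3]
  L <- config@nLevels
  margin <- max(2L, round(0.04 * R))
  avail <- R - 2L * margin
  hb <- floor(avail / (L + 0.45 * (L - 1)))
  hd <- max(3L, floor(0.45 * hb))
  if (hb < 4L)
    stop("imageShape rows too small for ", L, " vertebral levels")
  c0 <- max(1L, round(0.18 * Cc))
  wb <- max(5L, round(0.38 * Cc))
  c1 <- min(Cc, c0 + wb - 1L)
  lab2d <- matrix(0L, R, Cc)
  # bodies, bottom-up: level 1 (S1) lowest
  bottom <- R - margin
  for (lev in seq_len(L)) {
    r1 <- bottom; r0 <- bottom - hb + 1L
    lab2d[r0:r1, c0:c1] <- lev
    if (lev < L) {
      # lens-shaped disk between body lev and lev+1
      dr1 <- r0 - 1L; dr0 <- r0 - hd
      rc <- (dr0 + dr1) / 2
      cc_ <- (c0 + c1) / 2
      a_ <- (c1 - c0) / 2 + 1
      b_ <- hd / 2 + 0.25
      for (rr in dr0:dr1) for (cc2 in c0:c1) {
        if (((cc2 - cc_) / a_)^2 + ((rr - rc) / b_)^2 <= 1)
          lab2d[rr, cc2] <- 100L + lev
      }
      bottom <- dr0 - 1L
    }
  }
  # posterior soft-tissue band
  p0 <- min(Cc, c1 + 2L)
  p1 <- min(Cc, p0 + max(3L, round(0.12 * Cc)))
  lab2d[margin:(R - margin), p0:p1][
    lab2d[margin:(R - margin), p0:p1] == 0L] <- 200L
  labels <- array(0L, dim = c(S, R, Cc))
  for (s in seq_len(S)) labels[s, , ] <- lab2d
  labels
}

# annulus mask for one disk: first and last fifths of its anterior-posterior
# (column) extent
diskAnnulusMask <- function(labels, diskCode) {
  m <- labels == diskCode
  if (!any(m)) stop("disk ", diskCode, " absent")
  cols <- which(apply(m, 3, any))
  lo <- min(cols); hi <- max(cols)
  extent <- hi - lo + 1L
  bin <- pmin(4L, floor((seq(lo, hi) - lo) / extent * 5))
  annCols <- seq(lo, hi)[bin %in% c(0L, 4L)]
  ann <- m
  ann[, , setdiff(seq_len(dim(m)[3]), annCols)] <- FALSE
  ann
}

#' Generate one synthetic spine subject
#'
#' Marrow voxels are a spatially correlated Gaussian random field (white
#' noise smoothed at scale `textureCorrLen`, then exactly re-centred and
#' re-scaled over the marrow voxels to the configured mean and SD). Disks get
#' a bright nucleus and darker annulus (outer anterior--posterior fifths).
#' The whole volume is then perturbed by a per-subject global affine map
#' (offset, scale drawn from the configured ranges) and i.i.d. Gaussian
#' noise. Labels are exact ground truth.
#'
#' @param config a [PhantomConfig-class].
#' @param diseaseStatus 0 (control) or 1 (diseased).
#' @param seed integer RNG seed for this subject's stream.
#' @param subjectId identifier string.
#' @return a [SpineSubject-class].
#' @export
generateSubject <- function(config, diseaseStatus, seed = config@seed,
                            subjectId = sprintf("subj-%d", seed)) {
  validObject(config)
  diseaseStatus <- as.integer(diseaseStatus)
  stopifnot(diseaseStatus %in% c(0L, 1L))
  labels <- buildAnatomy(config)
  withSeed(seed, function() {
    vol <- array(0, dim = dim(labels))
    marrow <- labels >= 1L & labels <= 100L
    mMean <- if (diseaseStatus == 1L) config@marrowMeanDiseased else
      config@marrowMeanNormal
    mSd <- if (diseaseStatus == 1L) config@marrowTextureSdDiseased else
      config@marrowTextureSdNormal
    field <- array(rnorm(length(labels)), dim = dim(labels))
    field <- gaussianSmooth3D(field, config@textureCorrLen)
    fv <- field[marrow]
    if (sd(fv) > 0) fv <- (fv - mean(fv)) / sd(fv) else fv <- fv * 0
    vol[marrow] <- mMean + mSd * fv
    # disks: nucleus bright, annulus darker
    diskCodes <- sort(unique(labels[labels >= 101L & labels < 200L]))
    for (dc in diskCodes) {
      dm <- labels == dc
      vol[dm] <- config@diskNucleusMean
      ann <- diskAnnulusMask(labels, dc)
      vol[ann] <- config@annulusMean
    }
    vol[labels == 200L] <- 70
    # vendor affine + acquisition noise
    off <- runif(1, config@vendorOffsetRange[1], config@vendorOffsetRange[2])
    scl <- runif(1, config@vendorScaleRange[1], config@vendorScaleRange[2])
    vol <- scl * vol + off
    if (config@noiseSd > 0)
      vol <- vol + array(rnorm(length(vol), sd = config@noiseSd),
                         dim = dim(vol))
    new("SpineSubject",
        voxels = vol, labels = labels,
        spacing = c(3, 0.6, 0.6),
        diskDegenerated = rep(FALSE, max(0L, config@nLevels - 1L)),
        diseaseStatus = diseaseStatus,
        confounds = character(),
        subjectId = subjectId)
  })
}

#' Generate a cohort with exact class counts
#'
#' Subjects get independent per-subject RNG streams derived from `seed`;
#' focal lesions are inserted per `lesionProbs` within each subject's stream.
#' Controls come first, then diseased subjects.
#'
#' @param config a [PhantomConfig-class].
#' @param nControl,nDiseased class counts, >= 0.
#' @param seed master seed.
#' @return list of [SpineSubject-class] of length `nControl + nDiseased`.
#' @export
generateCohort <- function(config, nControl, nDiseased, seed = config@seed) {
  stopifnot(nControl >= 0, nDiseased >= 0)
  n <- nControl + nDiseased
  if (n == 0L) return(list())
  status <- c(rep(0L, nControl), rep(1L, nDiseased))
  # scrambled child seeds: arithmetic seed progressions can leave residual
  # correlation between generator streams
  subSeeds <- withSeed(seed, function() sample.int(2147483646L, n))
  lapply(seq_len(n), function(i) {
    si <- subSeeds[i]
    id <- sprintf("%s-%03d", if (status[i] == 1L) "dis" else "ctrl", i)
    subj <- generateSubject(config, status[i], seed = si, subjectId = id)
    for (k in seq_along(config@lesionProbs)) {
      p <- config@lesionProbs[k]
      if (p > 0 && withSeed(deriveSeed(si, k), function() runif(1)) < p)
        subj <- injectFocalLesion(subj, names(config@lesionProbs)[k],
                                  seed = deriveSeed(si, 100L + k))
    }
    subj
  })
}

#' Insert a focal confounding lesion into one vertebral level
#'
#' `fracture`: compresses the chosen level's row extent (collapse) and drops
#' the remaining marrow intensity. `hemangioma`: small blob brighter than the
#' level's pre-injection maximum. `modic`: intensity band adjacent to one
#' endplate. The affected level is chosen at random from the subject's
#' stream; `confounds` is updated.
#'
#' @param record a [SpineSubject-class].
#' @param lesionType one of `"fracture"`, `"hemangioma"`, `"modic"`.
#' @param seed RNG seed.
#' @return the modified [SpineSubject-class].
#' @export
injectFocalLesion <- function(record, lesionType, seed = 1L) {
  levs <- sort(unique(record@labels[record@labels >= 1L &
                                      record@labels <= 100L]))
  if (!length(levs)) stop("no vertebral level present")
  if (!lesionType %in% c("fracture", "hemangioma", "modic"))
    stop("unknown lesionType: ", lesionType)
  withSeed(seed, function() {
    lev <- levs[sample.int(length(levs), 1L)]
    m <- record@labels == lev
    vol <- record@voxels
    lab <- record@labels
    rows <- which(apply(m, 2, any))
    if (lesionType == "fracture") {
      h <- length(rows)
      drop_n <- max(1L, floor(0.4 * h))
      gone <- rows[seq(length(rows) - drop_n + 1L, length(rows))]
      gm <- m
      gm[, setdiff(seq_len(dim(m)[2]), gone), ] <- FALSE
      lab[gm] <- 200L
      vol[gm] <- 70
      keep <- lab == lev
      vol[keep] <- vol[keep] - 25
    } else if (lesionType == "hemangioma") {
      peak <- max(vol[m])
      idx <- which(m, arr.ind = TRUE)
      ctr <- idx[sample.int(nrow(idx), 1L), ]
      d <- sqrt((idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2 +
                  (idx[, 3] - ctr[3])^2)
      blob <- idx[d <= 2.5, , drop = FALSE]
      vol[blob] <- peak + 30
    } else { # modic: band at the inferior endplate
      band_n <- max(1L, floor(0.2 * length(rows)))
      band <- rows[seq(length(rows) - band_n + 1L, length(rows))]
      bm <- m
      bm[, setdiff(seq_len(dim(m)[2]), band), ] <- FALSE
      vol[bm] <- vol[bm] - 25
    }
    initialize(record, voxels = vol, labels = lab,
               confounds = unique(c(record@confounds, lesionType)))
  })
}
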