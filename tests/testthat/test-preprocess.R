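cfg0 <- phantomConfig(imageShape = c(3L, 60L, 48L), noiseSd = 0,
                      vendorOffsetRange = c(0, 0),
                      vendorScaleRange = c(1, 1))
subj0 <- generateSubject(cfg0, 0L, seed = 1L)

test_that("reference disk is the most cranial non-degenerated one", {
  expect_identical(selectReferenceDisk(subj0)$diskLevel, 5L)
  s <- subj0
  s@diskDegenerated <- c(FALSE, TRUE, TRUE, TRUE, TRUE)
  expect_identical(selectReferenceDisk(s)$diskLevel, 1L)
  s@diskDegenerated <- rep(TRUE, 5)
  expect_error(selectReferenceDisk(s), "no reference disk")
})

test_that("disk splitting partitions the anterior-posterior extent into 5 equal bins", {
  mkRoi <- function(cols, nCol = 20L) {
    m <- array(FALSE, dim = c(1L, 3L, nCol))
    m[1, , cols] <- TRUE
    structure(list(diskLevel = 1L, mask = m, apAxis = 3L), class = "DiskROI")
  }
  # width 10 (cols 1..10): annulus = cols {1,2,9,10}
  sp <- splitDiskRegions(mkRoi(1:10))
  annCols <- which(apply(sp$annulus, 3, any))
  expect_identical(annCols, c(1L, 2L, 9L, 10L))
  # width 11: every voxel in exactly one bin; bins cover the roi
  sp11 <- splitDiskRegions(mkRoi(1:11))
  roi <- mkRoi(1:11)$mask
  expect_true(all(sp11$bins[roi] %in% 1:5))
  expect_true(all(sp11$bins[!roi] == 0L))
  expect_identical(sum(sp11$bins > 0L), sum(roi))
  # real phantom disk: union of bins = roi, bins disjoint by construction
  roiP <- selectReferenceDisk(subj0)
  spP <- splitDiskRegions(roiP)
  expect_identical(spP$bins > 0L, roiP$mask)
  # too narrow to split
  expect_error(splitDiskRegions(mkRoi(1:4)), "too small")
})

test_that("disk normalization subtracts the annulus mean and is shift-invariant", {
  roi <- selectReferenceDisk(subj0)
  v <- voxels(subj0)
  nv <- normalizeByDisk(v, roi)
  ann <- splitDiskRegions(roi)$annulus
  expect_lt(abs(mean(nv[ann])), 1e-6)
  # shift invariance
  expect_equal(normalizeByDisk(v + 17.3, roi), nv)
  # idempotence
  expect_equal(normalizeByDisk(nv, roi), nv)
  # constant volume -> all zero
  cv <- array(42, dim(v))
  expect_true(all(normalizeByDisk(cv, roi) == 0))
  # arithmetic: voxel 50 under annulus mean 37.5 becomes 12.5
  av <- array(37.5, dim(v)); av[1, 1, 1] <- 50
  av[ann] <- 37.5
  expect_equal(normalizeByDisk(av, roi)[1, 1, 1], 12.5)
})

test_that("automatic seeds respect the anatomy", {
  s0 <- autoSeeds(subj0, erosionRadius = 0L)
  marrow <- anatomyLabels(subj0) >= 1L & anatomyLabels(subj0) <= 100L
  expect_identical(s0$label == 1L, marrow)
  s2 <- autoSeeds(subj0, erosionRadius = 1L)
  expect_true(all(marrow[s2$label == 1L]))
  expect_true(any(s2$label == 1L) && any(s2$label == 2L))
  # background seeds stay outside the marrow
  expect_true(all(!marrow[s2$label == 2L]))
  expect_error(autoSeeds(subj0, erosionRadius = 20L), "level")
})

test_that("GrowCut recovers a noise-free two-region partition exactly", {
  vol <- array(0, dim = c(2L, 8L, 8L))
  vol[, 1:4, ] <- 100
  seeds <- array(0L, dim(vol))
  seeds[1, 2, 4] <- 1L   # inside the bright region
  seeds[1, 7, 4] <- 2L   # inside the dark region
  res <- growCutSegment(vol, seeds, maxIters = 50L)
  expect_true(res@converged)
  expect_identical(maskArray(res), vol == 100)
})

test_that("GrowCut matches the brute-force oracle on a 4x4x2 toy volume", {
  set.seed(21)
  vol <- array(runif(32, 0, 100), dim = c(2L, 4L, 4L))
  seeds <- array(0L, dim(vol))
  seeds[1, 1, 1] <- 1L
  seeds[2, 4, 4] <- 2L
  res <- growCutSegment(vol, seeds, maxIters = 100L)
  ref <- bruteGrowCut(vol, seeds, maxIters = 100L)
  expect_true(res@converged && ref$converged)
  expect_identical(maskArray(res), ref$lab == 1L)
  expect_identical(res@iterations, ref$iterations)
})

test_that("seeded voxels never change label and strength stays in [0,1]", {
  set.seed(33)
  vol <- array(runif(16^3), dim = c(16L, 16L, 16L))
  seeds <- array(0L, dim(vol))
  idx1 <- cbind(sample(16, 5, TRUE), sample(16, 5, TRUE), sample(16, 5, TRUE))
  idx2 <- cbind(sample(16, 5, TRUE), sample(16, 5, TRUE), sample(16, 5, TRUE))
  seeds[idx1] <- 1L
  seeds[idx2[seeds[idx2] == 0L, , drop = FALSE]] <- 2L
  res <- growCutSegment(vol, seeds, maxIters = 500L)
  expect_true(res@converged)
  expect_lte(res@iterations, 500L)
  expect_true(all(maskArray(res)[seeds == 1L]))
  expect_true(all(!maskArray(res)[seeds == 2L]))
})

test_that("all-foreground seeding returns the whole volume immediately", {
  vol <- array(runif(8), dim = c(2L, 2L, 2L))
  seeds <- array(1L, dim(vol))
  res <- growCutSegment(vol, seeds, maxIters = 10L)
  expect_true(all(maskArray(res)))
  expect_identical(res@iterations, 1L)
  expect_true(res@converged)
})

test_that("degenerate GrowCut inputs error or warn as declared", {
  vol <- array(5, dim = c(2L, 2L, 2L))
  seeds <- array(0L, dim(vol)); seeds[1, 1, 1] <- 1L; seeds[2, 2, 2] <- 2L
  expect_error(growCutSegment(vol, seeds), "zero intensity range")
  vol2 <- array(runif(8), dim = c(2L, 2L, 2L))
  expect_warning(growCutSegment(vol2, seeds, maxIters = 1L), "fixpoint")
})

test_that("segmentation Dice against ground truth is high on phantoms", {
  cfg <- phantomConfig(imageShape = c(3L, 60L, 48L), noiseSd = 3)
  s <- generateSubject(cfg, 1L, seed = 17L)
  pp <- preprocessSubject(s, erosionRadius = 1L)
  truth <- anatomyLabels(s) >= 1L & anatomyLabels(s) <= 100L
  expect_gte(diceCoefficient(maskArray(pp$mask), truth), 0.95)
})
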