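test_that("noise-free construction puts marrow exactly at the configured mean", {
  cfg <- testPhantomConfig(noiseSd = 0, vendorOffsetRange = c(0, 0),
                           vendorScaleRange = c(1, 1))
  s <- generateSubject(cfg, 0L, seed = 7L)
  marrow <- anatomyLabels(s) >= 1L & anatomyLabels(s) <= 100L
  # field is exactly re-centred over marrow voxels
  expect_equal(mean(voxels(s)[marrow]), cfg@marrowMeanNormal)
  expect_equal(sd(voxels(s)[marrow]), cfg@marrowTextureSdNormal)
  d <- generateSubject(cfg, 1L, seed = 7L)
  expect_equal(mean(voxels(d)[marrow]), cfg@marrowMeanDiseased)
})

test_that("generation is bit-identical under a fixed seed", {
  cfg <- testPhantomConfig()
  a <- generateSubject(cfg, 1L, seed = 42L)
  b <- generateSubject(cfg, 1L, seed = 42L)
  expect_identical(voxels(a), voxels(b))
  expect_identical(anatomyLabels(a), anatomyLabels(b))
  ca <- generateCohort(cfg, 3, 2, seed = 9L)
  cb <- generateCohort(cfg, 3, 2, seed = 9L)
  expect_identical(lapply(ca, voxels), lapply(cb, voxels))
})

test_that("cohort composition is exact", {
  cfg <- testPhantomConfig()
  expect_identical(generateCohort(cfg, 0, 0), list())
  co <- generateCohort(cfg, 5, 7, seed = 2L)
  expect_length(co, 12L)
  expect_equal(sum(vapply(co, diseaseStatus, integer(1))), 7L)
  ids <- vapply(co, subjectId, character(1))
  expect_false(any(duplicated(ids)))
})

test_that("configured class contrast is detectable in disk-normalized marrow means", {
  # diseased mean set 3 noise-SDs below normal; Welch t-test on per-subject
  # disk-normalized marrow means over 40 + 40 subjects
  cfg <- testPhantomConfig(noiseSd = 5,
                           marrowMeanDiseased = 150 - 3 * 5,
                           marrowMeanNormal = 150)
  co <- generateCohort(cfg, 40, 40, seed = 31L)
  mns <- vapply(co, function(s) {
    n <- normalizeSubject(s)
    m <- anatomyLabels(n) >= 1L & anatomyLabels(n) <= 100L
    mean(voxels(n)[m])
  }, numeric(1))
  lab <- vapply(co, diseaseStatus, integer(1))
  p <- t.test(mns[lab == 0L], mns[lab == 1L])$p.value
  expect_lt(p, 0.01)
})

test_that("focal lesions alter exactly one level as declared", {
  cfg <- testPhantomConfig(noiseSd = 0, vendorOffsetRange = c(0, 0),
                           vendorScaleRange = c(1, 1))
  s <- generateSubject(cfg, 0L, seed = 3L)
  levs <- 1:6
  pre_max <- vapply(levs, function(l) max(voxels(s)[anatomyLabels(s) == l]),
                    numeric(1))
  h <- injectFocalLesion(s, "hemangioma", seed = 11L)
  post_max <- vapply(levs, function(l) max(voxels(h)[anatomyLabels(h) == l]),
                     numeric(1))
  expect_equal(sum(post_max > pre_max + 1), 1L)
  expect_identical(confounds(h), "hemangioma")

  rowExtent <- function(subj, l) {
    m <- anatomyLabels(subj) == l
    diff(range(which(apply(m, 2, any)))) + 1L
  }
  pre_ext <- vapply(levs, function(l) rowExtent(s, l), integer(1))
  f <- injectFocalLesion(s, "fracture", seed = 12L)
  post_ext <- vapply(levs, function(l) rowExtent(f, l), integer(1))
  expect_equal(sum(post_ext < pre_ext), 1L)
  expect_error(injectFocalLesion(s, "osteophyte"), "unknown")
})

test_that("zero lesion probabilities leave all confounds empty", {
  cfg <- testPhantomConfig()
  co <- generateCohort(cfg, 2, 2, seed = 5L)
  expect_true(all(vapply(co, function(s) length(confounds(s)) == 0L,
                         logical(1))))
  cfg2 <- testPhantomConfig(lesionProbs = c(fracture = 1, hemangioma = 0,
                                            modic = 0))
  co2 <- generateCohort(cfg2, 1, 1, seed = 5L)
  expect_true(all(vapply(co2, function(s) "fracture" %in% confounds(s),
                         logical(1))))
})

test_that("invalid configurations are rejected", {
  expect_error(phantomConfig(noiseSd = -1), "SD")
  expect_error(phantomConfig(nLevels = 0L), "nLevels")
  expect_error(phantomConfig(imageShape = c(0L, 10L, 10L)), "imageShape")
  expect_error(phantomConfig(lesionProbs = c(2, 0, 0)), "lesionProbs")
})

test_that("subjects round-trip losslessly through NIfTI + JSON sidecar", {
  cfg <- testPhantomConfig()
  s <- generateSubject(cfg, 1L, seed = 8L)
  s <- injectFocalLesion(s, "modic", seed = 1L)
  stem <- file.path(tempdir(), "subjA")
  saveSubject(s, stem)
  r <- loadSubject(stem)
  # float32 on disk: compare at float32 precision
  expect_equal(voxels(r), voxels(s), tolerance = 1e-6)
  expect_identical(anatomyLabels(r), anatomyLabels(s))
  expect_true(is.integer(anatomyLabels(r)))
  expect_identical(diseaseStatus(r), 1L)
  expect_identical(confounds(r), "modic")
  # truncated volume file -> I/O error naming the file
  con <- file(paste0(stem, "_vol.nii.gz"), "wb")
  writeBin(raw(10), con); close(con)
  expect_error(loadSubject(stem), "vol")
  expect_error(loadSubject(file.path(tempdir(), "nope")), "missing file")
})
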