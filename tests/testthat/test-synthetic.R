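test_that("scene generation is deterministic and matches the texture model", {
  cfg <- SceneConfig(seed = 11)
  s1 <- generateScene(cfg)
  s2 <- generateScene(cfg)
  expect_identical(s1$image, s2$image)

  # pure floor: intensity SD matches the texture model (0.035) within 10%
  floorOnly <- generateScene(SceneConfig(nAnimals = 0, seed = 12))
  expect_equal(sd(floorOnly$image), 0.035, tolerance = 0.1)
  expect_equal(mean(floorOnly$image), 0.2, tolerance = 0.05)
  expect_equal(nrow(floorOnly$blobs), 0L)
})

test_that("blobs form the requested number of connected components", {
  skip_if_not_installed("EBImage")
  s <- generateScene(SceneConfig(size = c(256, 256), nAnimals = 11,
                                 seed = 13))
  expect_equal(nrow(s$blobs), 11L)
  lab <- EBImage::bwlabel(s$image > 0.4)
  expect_equal(max(lab), 11)
})

test_that("smooth fields respect the magnitude bound and spacing ordering", {
  z <- generateSmoothField(c(32, 32), 0, seed = 1)
  expect_true(all(fieldArray(z) == 0))

  # |phi| bound over 100 random draws
  worst <- 0
  for (s in 1:100) {
    v <- fieldArray(generateSmoothField(c(24, 24), 5, spacing = 8, seed = s))
    worst <- max(worst, max(sqrt(v[, , 1]^2 + v[, , 2]^2)))
  }
  expect_lte(worst, 5 + 1e-12)

  # wider control spacing gives a smoother field (smaller regularizer)
  regs <- sapply(c(4, 8, 16), function(sp)
    diffusionRegularizer(generateSmoothField(c(64, 64), 6, spacing = sp,
                                             seed = 99)))
  expect_true(all(diff(regs) < 0))
})

test_that("ground-truth pairs are self-consistent through the known maps", {
  scene <- generateScene(SceneConfig(seed = 21))

  # degenerate settings: the pre-registered view is the fixed view, bitwise
  p0 <- generateViewPair(scene, homographyMagnitude = 0,
                         residualMagnitude = 0, illuminationDelta = 0,
                         seed = 22)
  expect_identical(p0@movingPrereg, p0@fixed)
  expect_identical(p0@movingRaw, p0@fixed)
  expect_equal(computeTRE(fixedPoints(p0@landmarks),
                          movingPoints(p0@landmarks)), 0)

  # residual magnitude 6: pre-registration TRE lands in [1, 6] px on average
  tres <- sapply(1:8, function(s)
    computeTRE(fixedPoints(generateViewPair(scene, residualMagnitude = 6,
                                            seed = s)@landmarks),
               movingPoints(generateViewPair(scene, residualMagnitude = 6,
                                             seed = s)@landmarks)))
  expect_gte(mean(tres), 1)
  expect_lte(mean(tres), 6)

  # composing the true homography and residual field recovers the fixed
  # landmarks within 0.5 px, across many seeds
  worst <- 0
  for (s in 1:50) {
    pair <- generateViewPair(scene, seed = s)
    viaH <- mapPointsProjective(movingPoints(pair@landmarksRaw),
                                pair@trueHomography)
    mapped <- warpPointsDense(viaH, pair@trueResidualField)
    worst <- max(worst, max(sqrt(rowSums(
      (mapped - fixedPoints(pair@landmarks))^2))))
  }
  expect_lt(worst, 0.5)

  # labels honour the blob geometry: foreground inside blobs, background out
  pair <- generateViewPair(scene, seed = 60)
  pts <- fixedPoints(pair@landmarks)
  lab <- landmarkLabels(pair@landmarks)
  inBlob <- scene$blobMask[cbind(round(pts[, 2]) + 1, round(pts[, 1]) + 1)]
  expect_true(all(inBlob[lab == "foreground"]))
  expect_true(all(!inBlob[lab == "background"]))
})

test_that("difficulty grows with the residual magnitude", {
  scene <- generateScene(SceneConfig(seed = 31))
  pre <- sapply(c(2, 6, 12), function(m) {
    mean(sapply(1:6, function(s) {
      p <- generateViewPair(scene, residualMagnitude = m, seed = 400 + s)
      computeTRE(fixedPoints(p@landmarks), movingPoints(p@landmarks))
    }))
  })
  expect_true(all(diff(pre) > 0))
})

test_that("dataset splits are disjoint, deterministic and annotated", {
  d1 <- generateDataset(3, 2, 1, seed = 41)
  d2 <- generateDataset(3, 2, 1, seed = 41)
  expect_identical(d1@manifest, d2@manifest)
  expect_identical(d1@test[[1]]@fixed, d2@test[[1]]@fixed)

  # no scene seed is shared between splits
  m <- d1@manifest
  expect_false(any(duplicated(m$sceneSeed)))
  expect_false(any(duplicated(m$pairSeed)))

  # a (0, 0, 1) split yields a single annotated test record
  single <- generateDataset(0, 0, 1, seed = 42)
  expect_length(single@test, 1L)
  expect_s4_class(single@test[[1]]@landmarks, "PairedLandmarks")

  d3 <- generateDataset(3, 2, 1, seed = 43)
  expect_false(identical(d1@manifest$sceneSeed, d3@manifest$sceneSeed))
})
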