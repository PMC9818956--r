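randomHomography <- function(seed) {
  # mild perspective terms keep the frame mostly in view when warping
  set.seed(seed)
  h <- diag(3) + matrix(rnorm(9, sd = 0.05), 3, 3)
  h[3, 1:2] <- rnorm(2, sd = 0.002)
  h[3, 3] <- 1
  Homography(h)
}

test_that("fitProjective recovers exact transforms from correspondences", {
  pts4 <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))

  # identity from coincident pairs
  h <- fitProjective(PairedLandmarks(pts4, pts4))
  expect_equal(homographyMatrix(h), diag(3), tolerance = 1e-9)

  # pure translation appears in the last column
  h2 <- fitProjective(PairedLandmarks(pts4 + rep(c(5, 3), each = 4), pts4))
  expect_equal(homographyMatrix(h2)[1:2, 3], c(5, 3), tolerance = 1e-9)
  expect_equal(homographyMatrix(h2)[1:2, 1:2], diag(2), tolerance = 1e-9)

  # generate-and-recover with 4 and 35 noiseless pairs
  for (n in c(4, 35)) {
    ht <- randomHomography(n)
    set.seed(n + 1)
    src <- cbind(runif(n, 0, 100), runif(n, 0, 100))
    dst <- mapPointsProjective(src, ht)
    hr <- fitProjective(PairedLandmarks(dst, src))
    expect_lt(max(abs(homographyMatrix(hr) - homographyMatrix(ht))), 1e-6)
  }

  expect_error(fitProjective(PairedLandmarks(pts4[1:3, ], pts4[1:3, ])),
               "at least 4")
  # collinear degenerate configuration
  line <- cbind(0:4, 2 * (0:4))
  expect_error(fitProjective(PairedLandmarks(line, line)), "degenerate")
})

test_that("mapPointsProjective matches homogeneous arithmetic", {
  pts <- cbind(c(1, 5, -2), c(0, 3, 7))
  expect_equal(mapPointsProjective(pts, Homography(diag(3))), unname(pts))

  tr <- Homography(rbind(c(1, 0, 4), c(0, 1, -2), c(0, 0, 1)))
  expect_equal(mapPointsProjective(pts, tr), unname(pts) + rep(c(4, -2), each = 3))

  h <- randomHomography(11)
  set.seed(12)
  p <- cbind(runif(50, 0, 64), runif(50, 0, 64))
  m <- homographyMatrix(h)
  want <- t(apply(p, 1, function(q) {
    v <- m %*% c(q, 1)
    v[1:2] / v[3]
  }))
  expect_equal(mapPointsProjective(p, h), want, tolerance = 1e-12)

  # forward then inverse is the identity
  back <- mapPointsProjective(mapPointsProjective(p, h), invertHomography(h))
  expect_lt(max(abs(back - p)), 1e-9)
})

test_that("warpImageProjective backward-samples through the inverse map", {
  img <- randImage(16, seed = 20)
  expect_identical(warpImageProjective(img, Homography(diag(3))), img)

  # integer translation equals an index shift with zero fill
  tr <- Homography(rbind(c(1, 0, 3), c(0, 1, 2), c(0, 0, 1)))
  out <- warpImageProjective(img, tr)
  oracle <- matrix(0, 16, 16)
  oracle[3:16, 4:16] <- img[1:14, 1:13]   # shifted by (dx=3, dy=2)
  expect_equal(out, oracle, tolerance = 1e-12)

  # constant image stays constant inside the mapped region
  const <- matrix(0.4, 16, 16)
  h <- randomHomography(21)
  outc <- warpImageProjective(const, h)
  expect_equal(outc[5:12, 5:12], const[5:12, 5:12], tolerance = 1e-9)
})

test_that("projective pre-registration reduces raw-view landmark error", {
  scene <- generateScene(SceneConfig(seed = 31))
  pair <- generateViewPair(scene, homographyMagnitude = 8,
                           residualMagnitude = 4, seed = 32)
  raw <- pair@landmarksRaw
  before <- computeTRE(fixedPoints(raw), movingPoints(raw))
  after <- computeTRE(fixedPoints(raw),
                      mapPointsProjective(movingPoints(raw),
                                          pair@trueHomography))
  expect_lte(after, before)
})
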