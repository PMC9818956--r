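test_that("distortPoints implements the radial polynomial", {
  # identity with zero coefficients
  m0 <- DistortionModel()
  pts <- cbind(c(0, 3.5, -2, 100), c(0, -1.2, 7, 50))
  expect_equal(distortPoints(pts, m0), unname(pts))

  # hand-computed single point: center (0,0), scale 1, k1 = 1, point (1,0)
  m1 <- DistortionModel(k1 = 1)
  expect_equal(distortPoints(cbind(1, 0), m1), cbind(2, 0))

  # grid of 25 points against the scalar oracle
  m <- DistortionModel(k1 = -0.1, k2 = 0.01, center = c(32, 24), scale = 40)
  g <- as.matrix(expand.grid(x = seq(0, 63, length.out = 5),
                             y = seq(0, 47, length.out = 5)))
  got <- distortPoints(g, m)
  want <- t(apply(g, 1, distortOracle, k1 = -0.1, k2 = 0.01, k3 = 0,
                  center = c(32, 24), scale = 40))
  expect_equal(got, unname(want), tolerance = 1e-12)

  expect_error(distortPoints(cbind(NA, 1), m0), "non-finite")
})

test_that("undistortPoints inverts distortion to sub-micron precision", {
  m0 <- DistortionModel(k1 = 0, k2 = 0, center = c(10, 10), scale = 20)
  pts <- cbind(c(1, 5), c(2, 9))
  expect_equal(undistortPoints(pts, m0), unname(pts))

  # roundtrip over 100 random in-frame points
  m <- DistortionModel(k1 = -0.1, k2 = 0.01, center = c(32, 32), scale = 48)
  set.seed(5)
  p <- cbind(runif(100, 0, 63), runif(100, 0, 63))
  q <- undistortPoints(distortPoints(p, m), m)
  expect_lt(max(abs(q - p)), 1e-6)

  # grossly non-invertible coefficients at a far-field point
  bad <- DistortionModel(k1 = 10, center = c(0, 0), scale = 1)
  expect_error(undistortPoints(cbind(50, 50), bad), "converge")
})

test_that("undistortImage resamples along the distortion map", {
  img <- randImage(32, seed = 2)
  expect_identical(undistortImage(img, DistortionModel()), img)

  # constant image stays constant where sampling is in-frame
  m <- DistortionModel(k1 = -0.05, center = c(15.5, 15.5), scale = 22)
  const <- matrix(0.6, 32, 32)
  out <- undistortImage(const, m)
  expect_equal(out[8:24, 8:24], const[8:24, 8:24], tolerance = 1e-12)

  # a bright point relocates where undistortPoints predicts
  img2 <- matrix(0, 64, 64)
  img2[31, 41] <- 1   # distorted-image position (x=40, y=30)
  m2 <- DistortionModel(k1 = -0.08, center = c(31.5, 31.5), scale = 45)
  out2 <- undistortImage(img2, m2)
  peak <- which(out2 == max(out2), arr.ind = TRUE)[1, ]
  pred <- undistortPoints(cbind(40, 30), m2)
  expect_lt(abs(peak["col"] - 1 - pred[1, 1]), 1)
  expect_lt(abs(peak["row"] - 1 - pred[1, 2]), 1)
})

test_that("applyMask zeroes outside-pen pixels and is idempotent", {
  img <- randImage(8, seed = 3)
  ones <- matrix(1, 8, 8)
  expect_equal(applyMask(img, ones), img)

  single <- matrix(0, 8, 8); single[3, 5] <- 1
  out <- applyMask(img, single)
  expect_equal(out[3, 5], img[3, 5])
  expect_equal(sum(out != 0), 1L)

  set.seed(4)
  rmask <- matrix(rbinom(64, 1, 0.5), 8, 8)
  rmask[1, 1] <- 1
  out2 <- applyMask(img, rmask)
  expect_equal(out2, img * rmask)                  # elementwise oracle
  expect_equal(applyMask(out2, rmask), out2)       # idempotent
  expect_error(applyMask(img, matrix(1, 4, 4)), "shape")
})

test_that("toGrayscale uses BT.601 luma weights and preserves range", {
  g <- randImage(6, seed = 6)
  rgb <- array(rep(g, 3), c(6, 6, 3))
  expect_equal(toGrayscale(rgb), g)

  red <- array(0, c(2, 2, 3)); red[, , 1] <- 1
  expect_equal(toGrayscale(red), matrix(0.299, 2, 2))

  set.seed(7)
  arr <- array(runif(48), c(4, 4, 3))
  want <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
  got <- toGrayscale(arr)
  expect_equal(got, want)
  expect_gte(min(got), min(arr))
  expect_lte(max(got), max(arr))
  expect_error(toGrayscale(array(0, c(4, 4, 2))), "3")
})
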