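test_that("similarity metrics match their definitions", {
  a <- randImage(8, seed = 1); b <- randImage(8, seed = 2)

  expect_equal(similarityMSE(a, a), 0)
  expect_equal(similarityMSE(matrix(1, 4, 4), matrix(0, 4, 4)), 1)
  expect_equal(similarityMSE(a, b), mean((a - b)^2))

  expect_equal(similaritySSD(a, a), 0)
  expect_equal(similaritySSD(matrix(1, 2, 2), matrix(0, 2, 2)), 4)
  expect_equal(similaritySSD(a, b), length(a) * similarityMSE(a, b),
               tolerance = 1e-12)

  expect_equal(similarityNCC(a, a), 1)
  expect_equal(similarityNCC(a, pmin(0.5 * a + 0.2, 1)), 1, tolerance = 1e-9)
  expect_equal(similarityNCC(a, 1 - a), -1, tolerance = 1e-9)
  expect_error(similarityNCC(a, matrix(0.5, 8, 8)), "variance")

  # optional mask restricts the averaged pixels
  mask <- matrix(0, 8, 8); mask[1:4, ] <- 1
  expect_equal(similarityMSE(a, b, mask), mean((a - b)[1:4, ]^2))
  expect_error(similarityMSE(a, b, matrix(0, 8, 8)), "mask")
})

test_that("diffusion regularizer matches the double-loop oracle", {
  expect_equal(diffusionRegularizer(constantField(6, 9, 2.5, -1)), 0)

  # dx(x, y) = x: every forward x-difference is 1
  H <- 5; W <- 7
  v <- array(0, c(H, W, 2))
  v[, , 1] <- matrix(rep(0:(W - 1), each = H), H, W)
  expect_equal(diffusionRegularizer(DeformationField(v)), H * (W - 1))

  set.seed(3)
  vr <- array(rnorm(H * W * 2, sd = 0.5), c(H, W, 2))
  expect_equal(diffusionRegularizer(DeformationField(vr)),
               diffusionOracle(vr), tolerance = 1e-12)

  # non-negative, zero iff constant
  expect_gt(diffusionRegularizer(DeformationField(vr)), 0)
})

test_that("composite losses decompose into their parts", {
  fixed <- randImage(12, seed = 4)
  z <- constantField(12, 12, 0, 0)
  expect_equal(unsupervisedLoss(fixed, fixed, z, lambda = 5), 0)

  moving <- randImage(12, seed = 5)
  f <- generateSmoothField(c(12, 12), 2, spacing = 4, seed = 6)
  expect_equal(unsupervisedLoss(fixed, moving, f, lambda = 0),
               similarityMSE(fixed, warpImageDense(moving, f)))
  expect_equal(unsupervisedLoss(fixed, moving, f, lambda = 0.3),
               similarityMSE(fixed, warpImageDense(moving, f)) +
                 0.3 * diffusionRegularizer(f, normalize = TRUE))
  expect_equal(unsupervisedLoss(fixed, moving, f, lambda = 0.1,
                                similarity = "ncc"),
               1 - similarityNCC(fixed, warpImageDense(moving, f)) +
                 0.1 * diffusionRegularizer(f, normalize = TRUE))
  # the normalized regularizer is the sum divided by the pixel count
  expect_equal(diffusionRegularizer(f, normalize = TRUE),
               diffusionRegularizer(f) / 144)
  expect_error(unsupervisedLoss(fixed, moving, f, similarity = "nope"),
               "unknown similarity")

  # landmark term: 3-4-5 squared
  lmk <- PairedLandmarks(cbind(0, 0), cbind(3, 4), "foreground")
  got <- semisupervisedLoss(fixed, moving, z, lmk, lambda = 0, mu = 1)
  expect_equal(got, similarityMSE(fixed, moving) + 25)
  expect_equal(semisupervisedLoss(fixed, moving, f, lmk, lambda = 0.2, mu = 0),
               unsupervisedLoss(fixed, moving, f, lambda = 0.2))
})

test_that("analytic gradients of both losses agree with finite differences", {
  # 8 x 8 toy network; subsample parameter coordinates per tensor
  cfg <- toyConfig(8, 8, levels = 3, filters = c(3, 4, 5))
  model <- gradCheckModel(cfg, seed = 7)
  fixed <- randImage(8, seed = 8); moving <- randImage(8, seed = 9)
  lmk <- PairedLandmarks(cbind(c(2.3, 5.1), c(3.7, 4.2)),
                         cbind(c(2.9, 4.6), c(3.1, 5.0)),
                         c("foreground", "background"))
  rec <- list(fixed = fixed, moving = moving, landmarks = lmk)
  lossOf <- function(theta, withLm) {
    out <- penreg:::netForward(theta, cfg, fixed, moving)
    if (withLm)
      semisupervisedLoss(fixed, moving, out$field, lmk, lambda = 0.01,
                         mu = 1, similarity = "mse")
    else unsupervisedLoss(fixed, moving, out$field, lambda = 0.01)
  }
  set.seed(10)
  for (withLm in c(FALSE, TRUE)) {
    lg <- penreg:::pairLossGrad(model@theta, cfg, rec, 0.01, 1, "mse", withLm)
    worst <- 0
    for (nm in names(model@theta)) {
      for (ix in sample(length(model@theta[[nm]]),
                        min(4, length(model@theta[[nm]])))) {
        h <- 1e-5
        tp <- model@theta; tp[[nm]][ix] <- tp[[nm]][ix] + h
        tm <- model@theta; tm[[nm]][ix] <- tm[[nm]][ix] - h
        fd <- (lossOf(tp, withLm) - lossOf(tm, withLm)) / (2 * h)
        an <- lg$grads[[nm]][ix]
        worst <- max(worst, abs(fd - an) / max(abs(fd), abs(an), 1e-8))
      }
    }
    expect_lt(worst, 1e-4)
  }
})
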