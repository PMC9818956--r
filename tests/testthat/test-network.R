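test_that("buildNetwork enforces divisibility and shapes the output field", {
  expect_error(NetworkConfig(levels = 3, filtersPerLevel = c(4, 8, 16),
                             inputSize = c(30, 64)),
               "divisible")

  cfg <- toyConfig(64, 64, levels = 3, filters = c(8, 16, 32))
  model <- buildNetwork(cfg, seed = 1)
  zero <- matrix(0, 64, 64)
  field <- predictField(model, zero, zero)
  expect_equal(dim(fieldArray(field)), c(64L, 64L, 2L))
  expect_true(all(is.finite(fieldArray(field))))

  # the full-scale preset builds a parameter state of the documented
  # topology (first layer: 3x3 kernels over 2 input channels, 32 kernels)
  shapes <- penreg:::thetaShapes(fullScaleNetworkConfig())
  expect_equal(shapes[["enc1a_w"]], c(3 * 3 * 2, 32))
  expect_equal(shapes[["bot_b_w"]], c(3 * 3 * 512, 512))
  expect_equal(shapes[["out_w"]], c(32, 2))
})

test_that("same seed and config give bit-identical parameters", {
  cfg <- toyConfig(16, 16)
  m1 <- buildNetwork(cfg, seed = 99)
  m2 <- buildNetwork(cfg, seed = 99)
  expect_identical(modelTheta(m1), modelTheta(m2))
  expect_identical(parameterChecksum(m1), parameterChecksum(m2))
  m3 <- buildNetwork(cfg, seed = 100)
  expect_false(identical(modelTheta(m1), modelTheta(m3)))
})

test_that("predictField is deterministic and validates shapes", {
  cfg <- toyConfig(16, 16)
  model <- buildNetwork(cfg, seed = 3)
  fixed <- randImage(16, seed = 4); moving <- randImage(16, seed = 5)
  f1 <- predictField(model, fixed, moving)
  f2 <- predictField(model, fixed, moving)
  expect_identical(fieldArray(f1), fieldArray(f2))
  expect_error(predictField(model, randImage(8), randImage(8)), "input size")
})

test_that("instance norm and residual blocks keep the backward pass exact", {
  # toggling the optional branches must not break gradient correctness
  for (variant in list(list(useInstanceNorm = FALSE, residualBlocks = FALSE),
                       list(useInstanceNorm = TRUE, residualBlocks = TRUE))) {
    cfg <- toyConfig(8, 8, levels = 2, filters = c(3, 4),
                     useInstanceNorm = variant$useInstanceNorm,
                     residualBlocks = variant$residualBlocks)
    model <- gradCheckModel(cfg, seed = 11)
    fixed <- randImage(8, seed = 12); moving <- randImage(8, seed = 13)
    rec <- list(fixed = fixed, moving = moving, landmarks = NULL)
    lg <- penreg:::pairLossGrad(model@theta, cfg, rec, 0.05, 0, "ssd", FALSE)
    set.seed(14)
    worst <- 0
    for (nm in names(model@theta)) {
      ix <- sample(length(model@theta[[nm]]), 1)
      h <- 1e-5
      tp <- model@theta; tp[[nm]][ix] <- tp[[nm]][ix] + h
      tm <- model@theta; tm[[nm]][ix] <- tm[[nm]][ix] - h
      lossAt <- function(th) {
        out <- penreg:::netForward(th, cfg, fixed, moving)
        unsupervisedLoss(fixed, moving, out$field, lambda = 0.05,
                         similarity = "ssd")
      }
      fd <- (lossAt(tp) - lossAt(tm)) / (2 * h)
      an <- lg$grads[[nm]][ix]
      worst <- max(worst, abs(fd - an) / max(abs(fd), abs(an), 1e-8))
    }
    expect_lt(worst, 1e-4)
  }
})
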