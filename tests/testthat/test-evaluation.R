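test_that("computeTRE matches hand-worked distances", {
  p <- cbind(c(1, 5), c(2, 7))
  expect_equal(computeTRE(p, p), 0)
  expect_equal(computeTRE(cbind(0, 0), cbind(3, 4)), 5)
  f <- cbind(c(0, 1), c(0, 1))
  m <- cbind(c(3, 1), c(4, 1))   # offsets (3,4) and (0,0)
  expect_equal(computeTRE(f, m), 2.5)
  expect_equal(computeTRE(f, m, convention = "squared"), 12.5)
  expect_error(computeTRE(p, cbind(1, 1)), "differ")

  # symmetry and Jensen: euclidean mean <= sqrt of squared mean
  set.seed(1)
  a <- matrix(runif(20, 0, 50), 10)
  b <- matrix(runif(20, 0, 50), 10)
  expect_equal(computeTRE(a, b), computeTRE(b, a))
  expect_lte(computeTRE(a, b), sqrt(computeTRE(a, b, "squared")))
})

test_that("evaluateMethod aggregates per-pair and per-label errors", {
  scene <- generateScene(SceneConfig(seed = 2))
  pairs <- lapply(3:5, function(s) generateViewPair(scene, seed = s))

  # identity = error already present after pre-registration
  rep0 <- evaluateMethod(identityMethod(), pairs)
  byHand <- mean(sapply(pairs, function(p)
    computeTRE(fixedPoints(p@landmarks), movingPoints(p@landmarks))))
  expect_equal(mean(perPairTre(rep0)), byHand)
  expect_equal(rep0@nPairs, 3L)
  expect_equal(rep0@nLandmarks, 18L)

  # the true residual field is an oracle: sub-pixel TRE on every pair
  oracle <- evaluateMethod(
    function(fixed, moving, pts, pair) warpPointsDense(pts, pair@trueResidualField),
    pairs)
  expect_lt(max(perPairTre(oracle)), 1)
  expect_true(all(perPairTre(oracle) <= perPairTre(rep0)))

  # all-foreground labels leave the background mean absent, not zero
  lmk <- PairedLandmarks(cbind(c(3, 6), c(3, 6)), cbind(c(4, 7), c(3, 6)),
                         "foreground")
  one <- list(list(fixed = scene$image, moving = scene$image,
                   landmarks = lmk))
  repFg <- evaluateMethod(identityMethod(), one)
  expect_true(is.na(backgroundTre(repFg)))
  expect_false(is.na(foregroundTre(repFg)))
})

test_that("compareMethods selects the right test branch", {
  # identical samples: degenerate, p = 1 with a warning
  a <- c(5, 6, 7, 8, 9, 10, 11, 12, 13, 14)
  expect_warning(res <- compareMethods(a, a), "zero")
  expect_equal(res@pValue, 1)

  # large constant shift: clearly significant
  set.seed(3)
  b <- rnorm(10, mean = 10, sd = 0.5)
  res2 <- compareMethods(b, b + 20)
  expect_lt(res2@pValue, 0.05)
  # cross-check against the directly selected test
  direct <- if (res2@testUsed == "paired_t")
    t.test(b, b + 20, paired = TRUE)$p.value
  else wilcox.test(b, b + 20, paired = TRUE, exact = FALSE)$p.value
  expect_equal(res2@pValue, direct)

  # Gaussian samples take the t-test branch
  set.seed(4)
  g1 <- rnorm(30, 10); g2 <- rnorm(30, 10.5)
  resG <- compareMethods(g1, g2)
  expect_identical(resG@testUsed, "paired_t")

  # heavy-tailed samples fall back to the signed-rank test
  set.seed(5)
  h1 <- exp(rnorm(30, 0, 1.5)); h2 <- h1 + rnorm(30, 0.2)
  resH <- compareMethods(h1, h2)
  expect_identical(resH@testUsed, "wilcoxon_signed_rank")

  expect_error(compareMethods(1:5, 1:4), "paired")
})

test_that("overlay composites fixed as green and the other as magenta", {
  g <- randImage(6, seed = 6)
  same <- makeOverlay(g, g)
  expect_equal(same[, , 1], same[, , 2])   # gray where equal
  expect_equal(same[, , 2], same[, , 3])

  green <- makeOverlay(matrix(1, 2, 2), matrix(0, 2, 2))
  expect_equal(green[, , 1], matrix(0, 2, 2))
  expect_equal(green[, , 2], matrix(1, 2, 2))
  expect_equal(green[, , 3], matrix(0, 2, 2))

  magenta <- makeOverlay(matrix(0, 2, 2), matrix(1, 2, 2))
  expect_equal(magenta[, , 1], matrix(1, 2, 2))
  expect_equal(magenta[, , 2], matrix(0, 2, 2))
  expect_equal(magenta[, , 3], matrix(1, 2, 2))

  expect_error(makeOverlay(g, matrix(0.5, 3, 3)), "differ")
})
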