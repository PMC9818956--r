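test_that("one epoch on self-pairs does not increase the loss", {
  cfg <- toyConfig(16, 16)
  model <- buildNetwork(cfg, seed = 1)
  img <- randImage(16, seed = 2)
  pairs <- replicate(4, list(fixed = img, moving = img), simplify = FALSE)
  tc <- TrainConfig(learningRate = 1e-3, batchSize = 4, epochs = 2,
                    decayStartEpoch = 2, lambda = 0.01, seed = 5)
  out <- trainUnsupervised(model, pairs, tc)
  h <- trainingHistory(out)
  expect_lte(h$loss[nrow(h)], h$loss[1])
  expect_identical(trainingPhase(out), "unsupervised")
})

test_that("a small network learns a pure translation", {
  # moving(p) = fixed(p + (2, 1)); under the backward-warp convention the
  # field registering moving onto fixed is the constant (-2, -1)
  set.seed(7)
  scene <- generateScene(SceneConfig(size = c(32, 32), nAnimals = 3,
                                     seed = 8))
  fixed <- scene$image
  moving <- warpImageDense(fixed, constantField(32, 32, 2, 1))
  cfg <- toyConfig(32, 32, levels = 3, filters = c(8, 16, 32))
  model <- buildNetwork(cfg, seed = 9)
  tc <- TrainConfig(learningRate = 2e-3, batchSize = 1, epochs = 150,
                    decayStartEpoch = 100, lambda = 0.05, seed = 10)
  trained <- trainUnsupervised(model, list(list(fixed = fixed,
                                                moving = moving)), tc)
  v <- fieldArray(predictField(trained, fixed, moving))
  interior <- 9:24
  expect_lt(abs(mean(v[interior, interior, 1]) - (-2)), 1)
  expect_lt(abs(mean(v[interior, interior, 2]) - (-1)), 1)
  # and registration cannot be worse than no warp at the optimum
  reg <- registerPair(trained, fixed, moving)
  expect_lte(similarityMSE(fixed, reg$warped), similarityMSE(fixed, moving))
})

test_that("seeded training runs are bit-reproducible", {
  cfg <- toyConfig(16, 16)
  pairs <- lapply(1:6, function(i) list(fixed = randImage(16, seed = i),
                                        moving = randImage(16, seed = i + 50)))
  tc <- TrainConfig(learningRate = 1e-3, batchSize = 2, epochs = 3,
                    decayStartEpoch = 2, seed = 42)
  r1 <- trainUnsupervised(buildNetwork(cfg, seed = 4), pairs, tc)
  r2 <- trainUnsupervised(buildNetwork(cfg, seed = 4), pairs, tc)
  expect_identical(trainingHistory(r1)$loss, trainingHistory(r2)$loss)
  expect_identical(modelTheta(r1), modelTheta(r2))
})

test_that("transferWeights copies parameters and rejects mismatches", {
  cfg <- toyConfig(16, 16)
  # train a step first: transfer must accept parameters that have been
  # through the optimizer, not just freshly initialized ones
  src <- trainUnsupervised(
    buildNetwork(cfg, seed = 20),
    list(list(fixed = randImage(16, seed = 25),
              moving = randImage(16, seed = 26))),
    TrainConfig(learningRate = 1e-3, batchSize = 1, epochs = 1,
                decayStartEpoch = 1, seed = 27))
  dst <- transferWeights(src, cfg)
  expect_identical(parameterChecksum(dst), parameterChecksum(src))
  expect_identical(trainingPhase(dst), "unsupervised")

  other <- toyConfig(16, 16, filters = c(5, 6))
  expect_error(transferWeights(src, other), "enc1a_w")

  # transfer then a fine-tune pass with zero learning rate is a no-op
  lmk <- PairedLandmarks(cbind(4, 4), cbind(5, 5), "background")
  ann <- list(list(fixed = randImage(16, seed = 21),
                   moving = randImage(16, seed = 22), landmarks = lmk))
  tc0 <- TrainConfig(learningRate = 1e-12, batchSize = 1, epochs = 1,
                     decayStartEpoch = 1, seed = 23)
  ft <- fineTune(dst, ann, tc0)
  expect_equal(modelTheta(ft), modelTheta(dst), tolerance = 1e-9)
  expect_identical(trainingPhase(ft), "fine_tuned")
})

test_that("fineTune with mu = 0 reproduces the unsupervised trace", {
  cfg <- toyConfig(16, 16)
  lmk <- PairedLandmarks(cbind(c(3, 8), c(4, 9)), cbind(c(3, 8), c(4, 9)),
                         c("foreground", "background"))
  recs <- lapply(1:4, function(i) list(fixed = randImage(16, seed = i),
                                       moving = randImage(16, seed = i + 30),
                                       landmarks = lmk))
  tcU <- TrainConfig(learningRate = 1e-3, batchSize = 2, epochs = 3,
                     decayStartEpoch = 3, mu = 0, seed = 77)
  u <- trainUnsupervised(buildNetwork(cfg, seed = 6), recs, tcU)
  f <- fineTune(buildNetwork(cfg, seed = 6), recs, tcU)
  expect_equal(trainingHistory(u)$loss, trainingHistory(f)$loss,
               tolerance = 1e-12)
})

test_that("fineTune validates inputs and phases", {
  cfg <- toyConfig(16, 16)
  model <- buildNetwork(cfg, seed = 1)
  noLmk <- list(list(fixed = randImage(16, 1), moving = randImage(16, 2)))
  tc <- TrainConfig(epochs = 1, decayStartEpoch = 1, seed = 1)
  expect_error(fineTune(model, noLmk, tc), "landmark")
  model@trainingPhase <- "fine_tuned"
  expect_error(fineTune(model, noLmk, tc), "expects")
  expect_error(trainUnsupervised(model, list(), tc), "empty")
})

test_that("model checkpoints restore losslessly", {
  cfg <- toyConfig(16, 16)
  model <- buildNetwork(cfg, seed = 55)
  path <- tempfile(fileext = ".rds")
  saveModel(model, path)
  back <- loadModel(path)
  expect_identical(modelTheta(back), modelTheta(model))
  expect_identical(parameterChecksum(back), parameterChecksum(model))
  fixed <- randImage(16, seed = 56); moving <- randImage(16, seed = 57)
  expect_identical(fieldArray(predictField(back, fixed, moving)),
                   fieldArray(predictField(model, fixed, moving)))
  unlink(path)
})
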