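#' Radial lens distortion model
#'
#' Polynomial radial distortion with up to three coefficients. A point
#' `p` is first mapped to normalized coordinates `(p - center) / scale`,
#' scaled by `1 + k1 r^2 + k2 r^4 + k3 r^6` with `r` the normalized radius,
#' and mapped back to pixels. With all coefficients zero the model is the
#' identity. Only `k1` and `k2` are normally used for lens calibration;
#' `k3` is retained for completeness and defaults to 0.
#'
#' @slot k1,k2,k3 dimensionless radial coefficients.
#' @slot center principal point, `c(x, y)` in pixels.
#' @slot scale focal-equivalent normalization factor in pixels (> 0).
#' @export
setClass("DistortionModel",
  representation(k1 = "numeric", k2 = "numeric", k3 = "numeric",
                 center = "numeric", scale = "numeric"),
  prototype(k1 = 0, k2 = 0, k3 = 0, center = c(0, 0), scale = 1),
  validity = function(object) {
    if (length(object@scale) != 1L || !is.finite(object@scale) ||
        object@scale <= 0)
      return("'scale' must be a single positive number")
    if (length(object@center) != 2L || any(!is.finite(object@center)))
      return("'center' must be a finite (x, y) pair")
    for (k in c("k1", "k2", "k3"))
      if (length(slot(object, k)) != 1L || !is.finite(slot(object, k)))
        return(sprintf("'%s' must be a single finite number", k))
    TRUE
  })

#' @describeIn DistortionModel constructor.
#' @param k1,k2,k3 radial coefficients.
#' @param center principal point `c(x, y)` in pixels.
#' @param scale normalization factor in pixels.
#' @export
DistortionModel <- function(k1 = 0, k2 = 0, k3 = 0, center = c(0, 0),
                            scale = 1) {
  new("DistortionModel", k1 = as.numeric(k1), k2 = as.numeric(k2),
      k3 = as.numeric(k3), center = as.numeric(center),
      scale = as.numeric(scale))
}

setMethod("show", "DistortionModel", function(object) {
  cat(sprintf(
    "DistortionModel: k1=%g k2=%g k3=%g center=(%g, %g) scale=%g\n",
    object@k1, object@k2, object@k3, object@center[1L], object@center[2L],
    object@scale))
})

#' Projective transform (homography)
#'
#' A 3 x 3 invertible matrix acting on homogeneous image coordinates,
#' normalized so that the bottom-right entry is 1. Used as the linear
#' pre-registration mapping moving-view points into the fixed view.
#'
#' @slot matrix the normalized 3 x 3 matrix.
#' @export
setClass("Homography", representation(matrix = "matrix"),
  prototype(matrix = diag(3)),
  validity = function(object) {
    m <- object@matrix
    if (!is.numeric(m) || any(dim(m) != c(3L, 3L)) || any(!is.finite(m)))
      return("'matrix' must be a finite 3 x 3 numeric matrix")
    if (abs(m[3L, 3L] - 1) > 1e-8)
      return("'matrix' must be normalized so that [3,3] == 1")
    if (abs(det(m)) < 1e-12 || !is.finite(kappa(m)))
      return("'matrix' must be invertible")
    TRUE
  })

#' @describeIn Homography constructor; normalizes the matrix so its
#'   bottom-right entry is 1.
#' @param matrix a 3 x 3 numeric matrix (any nonzero scale).
#' @export
Homography <- function(matrix = diag(3)) {
  m <- as.matrix(matrix)
  if (any(dim(m) != c(3L, 3L))) stop("homography must be 3 x 3")
  if (!is.finite(m[3L, 3L]) || abs(m[3L, 3L]) < 1e-12)
    stop("homography cannot be normalized: [3,3] entry is (near) zero")
  new("Homography", matrix = m / m[3L, 3L])
}

#' @describeIn Homography the normalized 3 x 3 matrix.
#' @param h a `Homography`.
#' @export
homographyMatrix <- function(h) {
  stopifnot(is(h, "Homography"))
  h@matrix
}

setMethod("show", "Homography", function(object) {
  cat("Homography (moving -> fixed):\n")
  print(signif(object@matrix, 6))
})

#' Corresponding landmark pairs on a fixed/moving image pair
#'
#' Each row of `fixedPoints` corresponds to the same row of
#' `movingPoints`; `labels` classifies every pair as `"foreground"`
#' (on an animal) or `"background"` (on static pen structure).
#'
#' @slot fixedPoints n x 2 matrix of (x, y) pixels on the fixed image.
#' @slot movingPoints n x 2 matrix of (x, y) pixels on the moving image.
#' @slot labels character vector, one of `"foreground"`/`"background"` per pair.
#' @export
setClass("PairedLandmarks",
  representation(fixedPoints = "matrix", movingPoints = "matrix",
                 labels = "character"),
  validity = function(object) {
    f <- object@fixedPoints; m <- object@movingPoints
    if (!is.numeric(f) || ncol(f) != 2L) return("'fixedPoints' must be n x 2")
    if (!is.numeric(m) || ncol(m) != 2L) return("'movingPoints' must be n x 2")
    if (nrow(f) < 1L) return("at least one landmark pair is required")
    if (nrow(f) != nrow(m)) return("fixed and moving point counts differ")
    if (any(!is.finite(f)) || any(!is.finite(m)))
      return("landmark coordinates must be finite")
    if (length(object@labels) != nrow(f))
      return("'labels' must cover every pair")
    if (!all(object@labels %in% c("foreground", "background")))
      return("labels must be 'foreground' or 'background'")
    TRUE
  })

#' @describeIn PairedLandmarks constructor.
#' @param fixedPoints,movingPoints n x 2 matrices of (x, y) pixel coords.
#' @param labels per-pair `"foreground"`/`"background"` labels; a single
#'   value is recycled.
#' @export
PairedLandmarks <- function(fixedPoints, movingPoints,
                            labels = "background") {
  f <- checkPoints(fixedPoints, "fixedPoints")
  m <- checkPoints(movingPoints, "movingPoints")
  labels <- rep_len(as.character(labels), nrow(f))
  new("PairedLandmarks", fixedPoints = f, movingPoints = m, labels = labels)
}

#' @describeIn PairedLandmarks landmark coordinates on the fixed image.
#' @param x a `PairedLandmarks`.
#' @export
fixedPoints <- function(x) { stopifnot(is(x, "PairedLandmarks")); x@fixedPoints }

#' @describeIn PairedLandmarks landmark coordinates on the moving image.
#' @export
movingPoints <- function(x) { stopifnot(is(x, "PairedLandmarks")); x@movingPoints }

#' @describeIn PairedLandmarks per-pair labels.
#' @export
landmarkLabels <- function(x) { stopifnot(is(x, "PairedLandmarks")); x@labels }

setMethod("show", "PairedLandmarks", function(object) {
  cat(sprintf("PairedLandmarks: %d pairs (%d foreground, %d background)\n",
              nrow(object@fixedPoints),
              sum(object@labels == "foreground"),
              sum(object@labels == "background")))
})

setMethod("length", "PairedLandmarks", function(x) nrow(x@fixedPoints))

#' Dense per-pixel displacement field
#'
#' An H x W x 2 array of pixel displacements; channel 1 is `dx`
#' (columns), channel 2 is `dy` (rows). The field drives a backward warp:
#' the registered image at pixel `p` samples the moving image at
#' `p + field(p)`.
#'
#' @slot vectors H x W x 2 numeric array, finite entries.
#' @export
setClass("DeformationField", representation(vectors = "array"),
  validity = function(object) {
    v <- object@vectors
    if (length(dim(v)) != 3L || dim(v)[3L] != 2L)
      return("'vectors' must be an H x W x 2 array")
    if (any(!is.finite(v))) return("displacements must be finite")
    TRUE
  })

#' @describeIn DeformationField constructor.
#' @param vectors H x W x 2 array (dx, dy), in pixels.
#' @export
DeformationField <- function(vectors) {
  if (is.matrix(vectors)) stop("'vectors' must be H x W x 2, not a matrix")
  storage.mode(vectors) <- "double"
  new("DeformationField", vectors = vectors)
}

#' @describeIn DeformationField the raw H x W x 2 array.
#' @param field a `DeformationField`.
#' @export
fieldArray <- function(field) {
  stopifnot(is(field, "DeformationField"))
  field@vectors
}

#' @describeIn DeformationField x-displacement (columns) matrix.
#' @export
fieldDx <- function(field) fieldArray(field)[, , 1L, drop = TRUE]

#' @describeIn DeformationField y-displacement (rows) matrix.
#' @export
fieldDy <- function(field) fieldArray(field)[, , 2L, drop = TRUE]

setMethod("show", "DeformationField", function(object) {
  d <- dim(object@vectors)
  mag <- sqrt(object@vectors[, , 1L]^2 + object@vectors[, , 2L]^2)
  cat(sprintf("DeformationField %d x %d: |phi| mean %.3f px, max %.3f px\n",
              d[1L], d[2L], mean(mag), max(mag)))
})

#' Displacement-network architecture configuration
#'
#' Describes the U-Net style encoder--decoder that maps a stacked
#' (fixed, moving) 2-channel image to a 2-channel displacement field:
#' 3 x 3 convolutions, 2 x 2 max pooling per level, 2 x 2 transposed
#' convolution upsampling, skip concatenation (optionally instance
#' normalized), and a final 1 x 1 convolution with two kernels.
#'
#' @slot levels encoder depth (>= 2).
#' @slot filtersPerLevel integer vector of kernel counts per level
#'   (full scale: 32, 64, 128, 256, 512).
#' @slot kernelSize spatial extent of the convolution kernels (odd).
#' @slot activation `"leaky_relu"` or `"relu"`.
#' @slot actSlope negative-side slope for leaky ReLU.
#' @slot useInstanceNorm instance normalization on skip connections.
#' @slot residualBlocks identity shortcut around the second convolution of
#'   each level (off by default; the skip concatenation is always present).
#' @slot inputSize `c(H, W)`; both divisible by `2^(levels - 1)`.
#' @slot fieldClamp optional absolute clamp on the output displacements in
#'   pixels (`Inf` = no clamp).
#' @export
setClass("NetworkConfig",
  representation(levels = "integer", filtersPerLevel = "integer",
                 kernelSize = "integer", activation = "character",
                 actSlope = "numeric", useInstanceNorm = "logical",
                 residualBlocks = "logical", inputSize = "integer",
                 fieldClamp = "numeric"),
  validity = function(object) {
    if (object@levels < 2L) return("'levels' must be >= 2")
    if (length(object@filtersPerLevel) != object@levels)
      return("'filtersPerLevel' must have one entry per level")
    if (any(object@filtersPerLevel < 1L)) return("filter counts must be >= 1")
    if (object@kernelSize %% 2L != 1L) return("'kernelSize' must be odd")
    if (!object@activation %in% c("leaky_relu", "relu"))
      return("'activation' must be 'leaky_relu' or 'relu'")
    div <- 2L^(object@levels - 1L)
    if (any(object@inputSize %% div != 0L))
      return(sprintf("input size (%d, %d) must be divisible by 2^(levels-1) = %d",
                     object@inputSize[1L], object@inputSize[2L], div))
    if (object@fieldClamp <= 0) return("'fieldClamp' must be positive")
    TRUE
  })

#' @describeIn NetworkConfig constructor. The default is the desk-scale
#'   profile (64 x 64, 3 levels, 8/16/32 filters); `fullScaleNetworkConfig()`
#'   returns the full-scale preset.
#' @param levels encoder depth.
#' @param filtersPerLevel kernel counts, one per level.
#' @param kernelSize convolution kernel extent.
#' @param activation `"leaky_relu"` or `"relu"`.
#' @param actSlope leaky ReLU negative slope.
#' @param useInstanceNorm instance-normalize skip connections.
#' @param residualBlocks enable in-level identity shortcuts.
#' @param inputSize `c(H, W)` image size the network accepts.
#' @param fieldClamp absolute displacement clamp in pixels (`Inf` = none).
#' @export
NetworkConfig <- function(levels = 3, filtersPerLevel = c(8, 16, 32),
                          kernelSize = 3, activation = "leaky_relu",
                          actSlope = 0.2, useInstanceNorm = TRUE,
                          residualBlocks = FALSE, inputSize = c(64, 64),
                          fieldClamp = Inf) {
  new("NetworkConfig", levels = as.integer(levels),
      filtersPerLevel = as.integer(filtersPerLevel),
      kernelSize = as.integer(kernelSize), activation = activation,
      actSlope = as.numeric(actSlope),
      useInstanceNorm = isTRUE(useInstanceNorm),
      residualBlocks = isTRUE(residualBlocks),
      inputSize = as.integer(inputSize), fieldClamp = as.numeric(fieldClamp))
}

#' @describeIn NetworkConfig full-scale preset: 928 x 1408 inputs, 5
#'   levels with 32/64/128/256/512 filters. Not intended for CPU training.
#' @export
fullScaleNetworkConfig <- function() {
  NetworkConfig(levels = 5, filtersPerLevel = c(32, 64, 128, 256, 512),
                inputSize = c(928, 1408))
}

setMethod("show", "NetworkConfig", function(object) {
  cat(sprintf(
    "NetworkConfig: %d levels, filters [%s], %dx%d input, %s(%g), IN=%s\n",
    object@levels, paste(object@filtersPerLevel, collapse = ","),
    object@inputSize[1L], object@inputSize[2L], object@activation,
    object@actSlope, object@useInstanceNorm))
})

#' Displacement-network model: architecture plus parameter state
#'
#' @slot config the `NetworkConfig`.
#' @slot theta named list of parameter arrays, shapes fully determined by
#'   `config`.
#' @slot trainingPhase `"untrained"`, `"unsupervised"` or `"fine_tuned"`.
#' @slot history per-epoch training log (epoch, loss, lr, phase).
#' @export
setClass("RegistrationModel",
  representation(config = "NetworkConfig", theta = "list",
                 trainingPhase = "character", history = "data.frame"),
  validity = function(object) {
    if (!object@trainingPhase %in% c("untrained", "unsupervised", "fine_tuned"))
      return("invalid 'trainingPhase'")
    TRUE
  })

#' @describeIn RegistrationModel the architecture configuration.
#' @param model a `RegistrationModel`.
#' @export
modelConfig <- function(model) {
  stopifnot(is(model, "RegistrationModel"))
  model@config
}

#' @describeIn RegistrationModel the named list of parameter arrays.
#' @export
modelTheta <- function(model) {
  stopifnot(is(model, "RegistrationModel"))
  model@theta
}

#' @describeIn RegistrationModel the training phase label.
#' @export
trainingPhase <- function(model) {
  stopifnot(is(model, "RegistrationModel"))
  model@trainingPhase
}

#' @describeIn RegistrationModel per-epoch training log.
#' @export
trainingHistory <- function(model) {
  stopifnot(is(model, "RegistrationModel"))
  model@history
}

#' @describeIn RegistrationModel a scalar checksum of the parameter state
#'   (sum of squares plus sum), usable to verify weight transfer.
#' @export
parameterChecksum <- function(model) {
  th <- modelTheta(model)
  sum(vapply(th, function(w) sum(w * w) + sum(w), numeric(1L)))
}

setMethod("show", "RegistrationModel", function(object) {
  np <- sum(vapply(object@theta, length, integer(1L)))
  cat(sprintf("RegistrationModel (%s): %d parameters\n",
              object@trainingPhase, np))
  show(object@config)
})

#' Training hyper-parameters
#'
#' Defaults follow the full-scale training protocol (Adam, learning rate
#' 1e-4, minibatch 4, 200 epochs with linear learning-rate decay starting
#' after epoch 100); `deskTrainConfig()` gives the reduced profile used for
#' CPU-scale synthetic experiments.
#'
#' @slot learningRate initial Adam step size.
#' @slot batchSize image pairs per optimization step.
#' @slot epochs total training epochs.
#' @slot decayStartEpoch epoch at which linear decay to zero begins.
#' @slot lambda diffusion-regularization weight.
#' @slot mu landmark-loss weight (semi-supervised phase).
#' @slot similarity `"mse"`, `"ncc"` or `"ssd"`.
#' @slot seed RNG seed for shuffling and any stochastic component.
#' @slot verbose print per-epoch progress.
#' @export
setClass("TrainConfig",
  representation(learningRate = "numeric", batchSize = "integer",
                 epochs = "integer", decayStartEpoch = "integer",
                 lambda = "numeric", mu = "numeric", similarity = "character",
                 seed = "integer", verbose = "logical"),
  validity = function(object) {
    if (object@learningRate <= 0) return("'learningRate' must be > 0")
    if (object@batchSize < 1L) return("'batchSize' must be >= 1")
    if (object@decayStartEpoch < 1L || object@decayStartEpoch > object@epochs)
      return("'decayStartEpoch' must lie in [1, epochs]")
    if (!object@similarity %in% c("mse", "ncc", "ssd"))
      return("'similarity' must be one of 'mse', 'ncc', 'ssd'")
    if (object@lambda < 0) return("'lambda' must be >= 0")
    if (object@mu < 0) return("'mu' must be >= 0")
    TRUE
  })

#' @describeIn TrainConfig constructor.
#' @param learningRate,batchSize,epochs,decayStartEpoch,lambda,mu,similarity,seed,verbose
#'   see slots.
#' @export
TrainConfig <- function(learningRate = 1e-4, batchSize = 4, epochs = 200,
                        decayStartEpoch = 100, lambda = 0.01, mu = 1.0,
                        similarity = "mse", seed = 1, verbose = FALSE) {
  new("TrainConfig", learningRate = as.numeric(learningRate),
      batchSize = as.integer(batchSize), epochs = as.integer(epochs),
      decayStartEpoch = as.integer(decayStartEpoch),
      lambda = as.numeric(lambda), mu = as.numeric(mu),
      similarity = similarity, seed = as.integer(seed),
      verbose = isTRUE(verbose))
}

#' @describeIn TrainConfig reduced profile for 64 x 64 synthetic
#'   experiments: 50 epochs, decay from epoch 25, learning rate 1e-3.
#' @param ... overrides passed on to `TrainConfig()`.
#' @export
deskTrainConfig <- function(...) {
  args <- list(learningRate = 1e-3, batchSize = 4, epochs = 50,
               decayStartEpoch = 25, lambda = 0.01, mu = 1.0,
               similarity = "mse", seed = 1)
  override <- list(...)
  args[names(override)] <- override
  do.call(TrainConfig, args)
}

setMethod("show", "TrainConfig", function(object) {
  cat(sprintf(
    "TrainConfig: lr=%g batch=%d epochs=%d decay@%d lambda=%g mu=%g sim=%s seed=%d\n",
    object@learningRate, object@batchSize, object@epochs,
    object@decayStartEpoch, object@lambda, object@mu, object@similarity,
    object@seed))
})

#' Target registration error report
#'
#' @slot perPairTre TRE per image pair (pixels).
#' @slot foregroundTre mean over foreground landmarks pooled across pairs
#'   (`NA` when no foreground landmark exists).
#' @slot backgroundTre mean over background landmarks (`NA` if absent).
#' @slot overallTre mean over all landmarks pooled across pairs.
#' @slot convention `"euclidean"` (default) or `"squared"` distances.
#' @slot nPairs,nLandmarks counts underlying the report.
#' @export
setClass("TREReport",
  representation(perPairTre = "numeric", foregroundTre = "numeric",
                 backgroundTre = "numeric", overallTre = "numeric",
                 convention = "character", nPairs = "integer",
                 nLandmarks = "integer"),
  validity = function(object) {
    if (any(object@perPairTre < 0, na.rm = TRUE))
      return("TRE values must be non-negative")
    if (!object@convention %in% c("euclidean", "squared"))
      return("'convention' must be 'euclidean' or 'squared'")
    TRUE
  })

setMethod("show", "TREReport", function(object) {
  cat(sprintf(
    "TREReport (%s, %d pairs, %d landmarks): overall %.3f px [bg %.3f | fg %.3f]\n",
    object@convention, object@nPairs, object@nLandmarks, object@overallTre,
    object@backgroundTre, object@foregroundTre))
})

#' @describeIn TREReport overall pooled TRE.
#' @param report a `TREReport`.
#' @export
overallTre <- function(report) { stopifnot(is(report, "TREReport")); report@overallTre }

#' @describeIn TREReport per-pair TRE vector (input to paired tests).
#' @export
perPairTre <- function(report) { stopifnot(is(report, "TREReport")); report@perPairTre }

#' @describeIn TREReport foreground pooled TRE (`NA` if no foreground
#'   landmark).
#' @export
foregroundTre <- function(report) { stopifnot(is(report, "TREReport")); report@foregroundTre }

#' @describeIn TREReport background pooled TRE (`NA` if absent).
#' @export
backgroundTre <- function(report) { stopifnot(is(report, "TREReport")); report@backgroundTre }

#' Result of a paired statistical comparison of two methods
#'
#' Normality of each method's per-pair TRE sample is assessed by the
#' Shapiro--Wilk test; when both samples look normal (p > alpha) a paired
#' t-test is used, otherwise the Wilcoxon signed-rank test.
#'
#' @slot methodA,methodB method labels.
#' @slot normalityP Shapiro--Wilk p-values, named by method.
#' @slot testUsed `"paired_t"` or `"wilcoxon_signed_rank"`.
#' @slot pValue p-value of the selected paired test.
#' @export
setClass("ComparisonResult",
  representation(methodA = "character", methodB = "character",
                 normalityP = "numeric", testUsed = "character",
                 pValue = "numeric"),
  validity = function(object) {
    if (!object@testUsed %in% c("paired_t", "wilcoxon_signed_rank"))
      return("invalid 'testUsed'")
    if (length(object@pValue) != 1L || is.na(object@pValue) ||
        object@pValue < 0 || object@pValue > 1)
      return("'pValue' must be a single probability")
    TRUE
  })

setMethod("show", "ComparisonResult", function(object) {
  cat(sprintf(
    "ComparisonResult %s vs %s: %s, p = %.4g (Shapiro-Wilk p: %.3g, %.3g)\n",
    object@methodA, object@methodB, object@testUsed, object@pValue,
    object@normalityP[1L], object@normalityP[2L]))
})

#' Synthetic scene configuration
#'
#' Parameters of the generated pen scene: a dark textured floor with
#' brighter elliptical textured blobs standing in for the animals. The
#' defaults emulate the study conditions at desk scale: 64 x 64 frames and
#' 5 animals (a pen holds 10--11 animals at a frame area roughly 20x
#' larger).
#'
#' @slot size `c(H, W)` in pixels.
#' @slot nAnimals number of elliptical blobs.
#' @slot floorTextureScale spatial period of the floor texture in pixels.
#' @slot illuminationDelta amplitude of the affine (gain/bias) intensity
#'   difference between the two views.
#' @slot noiseSd standard deviation of additive Gaussian sensor noise on
#'   the moving view (0 = noise-free).
#' @slot seed RNG seed.
#' @export
setClass("SceneConfig",
  representation(size = "integer", nAnimals = "integer",
                 floorTextureScale = "numeric", illuminationDelta = "numeric",
                 noiseSd = "numeric", seed = "integer"),
  validity = function(object) {
    if (any(object@size < 8L)) return("scene must be at least 8 x 8")
    if (object@nAnimals < 0L) return("'nAnimals' must be >= 0")
    if (object@floorTextureScale <= 0) return("'floorTextureScale' must be > 0")
    if (object@illuminationDelta < 0) return("'illuminationDelta' must be >= 0")
    if (object@noiseSd < 0) return("'noiseSd' must be >= 0")
    TRUE
  })

#' @describeIn SceneConfig constructor.
#' @param size `c(H, W)`.
#' @param nAnimals blob count.
#' @param floorTextureScale floor texture period (px).
#' @param illuminationDelta view illumination difference amplitude.
#' @param noiseSd additive noise SD on the moving view.
#' @param seed RNG seed.
#' @export
SceneConfig <- function(size = c(64, 64), nAnimals = 5,
                        floorTextureScale = 8, illuminationDelta = 0.05,
                        noiseSd = 0, seed = 1) {
  new("SceneConfig", size = as.integer(size), nAnimals = as.integer(nAnimals),
      floorTextureScale = as.numeric(floorTextureScale),
      illuminationDelta = as.numeric(illuminationDelta),
      noiseSd = as.numeric(noiseSd), seed = as.integer(seed))
}

setMethod("show", "SceneConfig", function(object) {
  cat(sprintf(
    "SceneConfig: %dx%d, %d animals, texture %g px, illum %g, seed %d\n",
    object@size[1L], object@size[2L], object@nAnimals,
    object@floorTextureScale, object@illuminationDelta, object@seed))
})

#' Synthetic paired-view sample with known ground truth
#'
#' `fixed` is the front-view frame; `movingRaw` the side view before
#' pre-registration; `movingPrereg` the side view after warping by the
#' true homography (an ideal projective pre-registration). The true
#' residual field is the backward displacement field that registers
#' `movingPrereg` onto `fixed`; landmarks are mapped exactly through the
#' known transforms.
#'
#' @slot fixed,movingRaw,movingPrereg grayscale image matrices.
#' @slot trueHomography the moving-raw -> fixed projective map.
#' @slot trueResidualField backward `DeformationField` registering
#'   `movingPrereg` onto `fixed`.
#' @slot landmarks `PairedLandmarks` between `fixed` and `movingPrereg`.
#' @slot landmarksRaw `PairedLandmarks` between `fixed` and `movingRaw`.
#' @export
setClass("GroundTruthPair",
  representation(fixed = "matrix", movingRaw = "matrix",
                 movingPrereg = "matrix", trueHomography = "Homography",
                 trueResidualField = "DeformationField",
                 landmarks = "PairedLandmarks",
                 landmarksRaw = "PairedLandmarks"))

setMethod("show", "GroundTruthPair", function(object) {
  cat(sprintf("GroundTruthPair: %d x %d frames, %d landmark pairs\n",
              nrow(object@fixed), ncol(object@fixed),
              length(object@landmarks)))
  show(object@trueResidualField)
})

#' Train / fine-tune / test split of generated pairs
#'
#' @slot train list of pairs without landmark annotations.
#' @slot finetune,test lists of annotated pairs (`GroundTruthPair`).
#' @slot manifest data frame describing the split (and file paths when
#'   written to disk).
#' @export
setClass("DatasetSplit",
  representation(train = "list", finetune = "list", test = "list",
                 manifest = "data.frame"),
  validity = function(object) {
    ok <- function(p) is(p, "GroundTruthPair") || !is.null(p$landmarks)
    if (length(object@finetune) && !all(vapply(object@finetune, ok, logical(1L))))
      return("fine-tuning records must carry landmarks")
    if (length(object@test) && !all(vapply(object@test, ok, logical(1L))))
      return("test records must carry landmarks")
    TRUE
  })

setMethod("show", "DatasetSplit", function(object) {
  cat(sprintf("DatasetSplit: %d train / %d finetune / %d test pairs\n",
              length(object@train), length(object@finetune),
              length(object@test)))
})
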