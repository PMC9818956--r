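# Synthetic paired-view pen scenes with known ground-truth geometry.
#
# The generator emulates what the deformable stage sees on the farm
# recordings after preprocessing: a dark textured floor, brighter
# elliptical textured blobs standing in for the animals, two views
# related by a projective transform plus a smooth non-linear residual
# deformation, an affine illumination difference between the views, and
# exactly mapped foreground/background landmark pairs.

# Standardized smooth noise: coarse Gaussian control grid, bilinearly
# upsampled, then centered and scaled to unit variance.
smoothNoise <- function(H, W, scale) {
  nh <- ceiling((H - 1) / scale) + 1L
  nw <- ceiling((W - 1) / scale) + 1L
  ctrl <- matrix(rnorm(nh * nw), nh, nw)
  xs <- matrix(rep(seq_len(W) - 1, each = H), H, W) / scale
  ys <- matrix(rep(seq_len(H) - 1, W), H, W) / scale
  z <- .bilinear_sample(ctrl, xs, ys)
  (z - mean(z)) / sd(z)
}

ellipseMask <- function(H, W, cx, cy, a, b, angle, grow = 0) {
  x <- matrix(rep(seq_len(W) - 1, each = H), H, W) - cx
  y <- matrix(rep(seq_len(H) - 1, W), H, W) - cy
  xr <- cos(angle) * x + sin(angle) * y
  yr <- -sin(angle) * x + cos(angle) * y
  (xr / (a + grow))^2 + (yr / (b + grow))^2 <= 1
}

#' Generate a synthetic pen scene
#'
#' A dark textured floor (mean 0.2, SD 0.035, spatial period
#' `floorTextureScale`) with `nAnimals` brighter elliptical blobs, each
#' carrying its own texture and random orientation/aspect. Blobs are
#' placed with a guaranteed gap (no two blob masks touch), retrying up to
#' 60 positions per blob; if a blob cannot be placed a warning is issued
#' and the scene carries fewer blobs. Deterministic given `cfg@seed`.
#'
#' @param cfg a [SceneConfig].
#' @return `list(image, blobs, blobMask)`: the grayscale scene, a data
#'   frame of blob geometry (`cx, cy, a, b, angle`) and the logical
#'   foreground mask.
#' @export
generateScene <- function(cfg = SceneConfig()) {
  stopifnot(is(cfg, "SceneConfig"))
  validObject(cfg)
  H <- cfg@size[1L]; W <- cfg@size[2L]
  withSeed(cfg@seed, {
    img <- 0.2 + 0.035 * smoothNoise(H, W, cfg@floorTextureScale)
    img <- pmin(pmax(img, 0), 1)
    blobMask <- matrix(FALSE, H, W)
    blobs <- data.frame(cx = numeric(), cy = numeric(), a = numeric(),
                        b = numeric(), angle = numeric())
    placed <- 0L
    for (i in seq_len(cfg@nAnimals)) {
      ok <- FALSE
      for (attempt in seq_len(60L)) {
        a <- runif(1, 0.07, 0.11) * min(H, W)
        b <- runif(1, 0.50, 0.80) * a
        angle <- runif(1, 0, pi)
        cx <- runif(1, 0.12 * W, 0.88 * W)
        cy <- runif(1, 0.12 * H, 0.88 * H)
        m <- ellipseMask(H, W, cx, cy, a, b, angle)
        mGrown <- ellipseMask(H, W, cx, cy, a, b, angle, grow = 2.5)
        if (!any(mGrown & blobMask) && any(m)) {
          tex <- 0.65 + 0.05 * smoothNoise(H, W, max(2, cfg@floorTextureScale / 2)) +
            runif(1, -0.08, 0.08)
          img[m] <- pmin(pmax(tex[m], 0.45), 0.95)
          blobMask <- blobMask | m
          blobs <- rbind(blobs, data.frame(cx = cx, cy = cy, a = a, b = b,
                                           angle = angle))
          placed <- placed + 1L
          ok <- TRUE
          break
        }
      }
      if (!ok)
        warning(sprintf(
          "could only place %d of %d blobs without overlap", placed,
          cfg@nAnimals))
    }
    list(image = img, blobs = blobs, blobMask = blobMask)
  })
}

#' Generate a random smooth displacement field
#'
#' Draws a coarse control grid of displacement vectors uniform in the
#' disc of radius `maxDisplacement` at `spacing`-pixel intervals and
#' upsamples it by bilinear interpolation. Interpolated vectors are
#' convex combinations of the control vectors, so the field magnitude
#' `|phi|` never exceeds the requested bound, and smoothness grows with
#' the control-point spacing.
#'
#' @param size `c(H, W)` of the field.
#' @param maxDisplacement bound on `|dx|` and `|dy|` in pixels (>= 0).
#' @param spacing control-point spacing in pixels.
#' @param seed RNG seed.
#' @return a [DeformationField].
#' @export
generateSmoothField <- function(size, maxDisplacement, spacing = 16,
                                seed = 1L) {
  stopifnot(maxDisplacement >= 0, spacing > 0)
  H <- as.integer(size[1L]); W <- as.integer(size[2L])
  if (maxDisplacement == 0)
    return(DeformationField(array(0, c(H, W, 2L))))
  withSeed(seed, {
    nh <- ceiling((H - 1) / spacing) + 1L
    nw <- ceiling((W - 1) / spacing) + 1L
    xs <- matrix(rep(seq_len(W) - 1, each = H), H, W) / spacing
    ys <- matrix(rep(seq_len(H) - 1, W), H, W) / spacing
    r <- maxDisplacement * sqrt(runif(nh * nw))
    t <- runif(nh * nw, 0, 2 * pi)
    v <- array(0, c(H, W, 2L))
    v[, , 1L] <- .bilinear_sample(matrix(r * cos(t), nh, nw), xs, ys)
    v[, , 2L] <- .bilinear_sample(matrix(r * sin(t), nh, nw), xs, ys)
    DeformationField(v)
  })
}

#' Generate a ground-truth paired view from a scene
#'
#' Builds the two-camera observation of a scene: the fixed (front) view
#' is the scene itself; the moving (side) view is the scene seen through
#' a random projective transform (corner offsets up to
#' `homographyMagnitude` pixels) composed with a smooth residual
#' deformation of magnitude `residualMagnitude`, then shifted in
#' illumination by a random affine gain/bias of amplitude
#' `illuminationDelta` and optionally noised. `movingPrereg` is the side
#' view after warping by the *true* homography, i.e. after an ideal
#' projective pre-registration, so the deformable stage can be exercised
#' in isolation; `movingRaw` retains the unregistered view for end-to-end
#' runs. The residual field is constructed in the backward-warp
#' convention: `warpImageDense(movingPrereg, trueResidualField)`
#' reproduces the fixed image (up to resampling), and landmarks are
#' mapped exactly through the known transforms (3 on blobs, 3 on the
#' floor).
#'
#' @param scene output of [generateScene()].
#' @param homographyMagnitude corner-offset amplitude of the true
#'   homography, pixels (>= 0).
#' @param residualMagnitude bound on the residual field, pixels (>= 0).
#' @param illuminationDelta affine intensity-difference amplitude.
#' @param noiseSd additive Gaussian noise SD on the moving views.
#' @param fieldSpacing control-point spacing of the residual field.
#' @param nForeground,nBackground landmarks on blobs / on the floor.
#' @param seed RNG seed.
#' @return a [GroundTruthPair].
#' @export
generateViewPair <- function(scene, homographyMagnitude = 8,
                             residualMagnitude = 6,
                             illuminationDelta = 0.05, noiseSd = 0,
                             fieldSpacing = 16, nForeground = 3,
                             nBackground = 3, seed = 1L) {
  stopifnot(homographyMagnitude >= 0, residualMagnitude >= 0)
  fixed <- scene$image
  H <- nrow(fixed); W <- ncol(fixed)
  withSeed(seed, {
    fieldSeed <- sample.int(2147483646L, 1L)
    resField <- generateSmoothField(c(H, W), residualMagnitude,
                                    spacing = fieldSpacing, seed = fieldSeed)
    v <- resField@vectors
    X0 <- matrix(rep(seq_len(W) - 1, each = H), H, W)
    Y0 <- matrix(rep(seq_len(H) - 1, W), H, W)
    # invert p -> p + phi(p) on the pixel grid (fixed-point iteration)
    Xp <- X0; Yp <- Y0
    if (residualMagnitude > 0) {
      for (it in seq_len(25L)) {
        Xp <- X0 - .bilinear_sample(v[, , 1L], Xp, Yp)
        Yp <- Y0 - .bilinear_sample(v[, , 2L], Xp, Yp)
      }
      movingPrereg <- .bilinear_sample(fixed, Xp, Yp)
    } else movingPrereg <- fixed

    corners <- cbind(c(0, W - 1, W - 1, 0), c(0, 0, H - 1, H - 1))
    if (homographyMagnitude > 0) {
      movingCorners <- corners +
        matrix(runif(8, -homographyMagnitude, homographyMagnitude), 4L, 2L)
      trueH <- fitProjective(PairedLandmarks(corners, movingCorners))
    } else {
      runif(8)  # keep the RNG stream aligned across magnitude settings
      trueH <- Homography(diag(3))
    }
    if (homographyMagnitude > 0) {
      grid <- cbind(as.numeric(X0), as.numeric(Y0))
      src <- mapPointsProjective(grid, trueH)
      movingRaw <- .bilinear_sample(movingPrereg, matrix(src[, 1L], H, W),
                                    matrix(src[, 2L], H, W))
    } else movingRaw <- movingPrereg

    # affine illumination difference between the views (+ optional noise)
    gain <- 1 + runif(1, -illuminationDelta, illuminationDelta)
    bias <- runif(1, -illuminationDelta / 2, illuminationDelta / 2)
    shade <- function(m) {
      m <- gain * m + bias
      if (noiseSd > 0) m <- m + matrix(rnorm(length(m), sd = noiseSd),
                                       nrow(m))
      pmin(pmax(m, 0), 1)
    }
    movingPrereg <- shade(movingPrereg)
    movingRaw <- shade(movingRaw)

    # landmarks: exact correspondences through the known transforms
    hinv <- invertHomography(trueH)
    nBlob <- nrow(scene$blobs)
    if (nForeground > 0 && nBlob == 0)
      stop("foreground landmarks requested but the scene has no blobs")
    sampleLandmark <- function(fg) {
      for (attempt in seq_len(100L)) {
        if (fg) {
          b <- scene$blobs[sample.int(nBlob, 1L), ]
          t <- runif(1, 0, 2 * pi); rad <- sqrt(runif(1)) * 0.6
          xr <- rad * b$a * cos(t); yr <- rad * b$b * sin(t)
          p <- c(b$cx + cos(b$angle) * xr - sin(b$angle) * yr,
                 b$cy + sin(b$angle) * xr + cos(b$angle) * yr)
        } else {
          p <- c(runif(1, 3, W - 4), runif(1, 3, H - 4))
          if (scene$blobMask[round(p[2L]) + 1L, round(p[1L]) + 1L]) next
        }
        if (p[1L] < 2 || p[1L] > W - 3 || p[2L] < 2 || p[2L] > H - 3) next
        q <- p + sampleField(v, matrix(p, 1L))[1L, ]
        if (q[1L] < 1 || q[1L] > W - 2 || q[2L] < 1 || q[2L] > H - 2) next
        u <- mapPointsProjective(matrix(q, 1L), hinv)[1L, ]
        if (u[1L] < 0 || u[1L] > W - 1 || u[2L] < 0 || u[2L] > H - 1) next
        return(list(fixed = p, prereg = q, raw = u))
      }
      stop("could not place a landmark inside the frame after 100 attempts")
    }
    lms <- c(lapply(seq_len(nForeground), function(i) sampleLandmark(TRUE)),
             lapply(seq_len(nBackground), function(i) sampleLandmark(FALSE)))
    fixedPts <- do.call(rbind, lapply(lms, `[[`, "fixed"))
    preregPts <- do.call(rbind, lapply(lms, `[[`, "prereg"))
    rawPts <- do.call(rbind, lapply(lms, `[[`, "raw"))
    labels <- c(rep("foreground", nForeground), rep("background", nBackground))

    new("GroundTruthPair", fixed = fixed, movingRaw = movingRaw,
        movingPrereg = movingPrereg, trueHomography = trueH,
        trueResidualField = resField,
        landmarks = PairedLandmarks(fixedPts, preregPts, labels),
        landmarksRaw = PairedLandmarks(fixedPts, rawPts, labels))
  })
}

#' Generate a train / fine-tune / test dataset of paired views
#'
#' Draws disjoint per-pair scene and view seeds from `seed` and generates
#' `nTrain + nFinetune + nTest` ground-truth pairs under the same study
#' conditions. Training records are treated as unannotated; fine-tune and
#' test records carry landmarks. When `outDir` is given, images (PNG),
#' landmark CSVs and a JSON manifest are written to disk; the in-memory
#' split is returned either way.
#'
#' @param nTrain,nFinetune,nTest split sizes (>= 0).
#' @param baseCfg a [SceneConfig]; its seed slot is ignored in favour of
#'   the per-pair seeds derived from `seed`.
#' @param seed master RNG seed for the whole dataset.
#' @param outDir optional output directory.
#' @param homographyMagnitude,residualMagnitude,fieldSpacing view-pair
#'   generation parameters, see [generateViewPair()].
#' @return a [DatasetSplit].
#' @export
generateDataset <- function(nTrain, nFinetune, nTest,
                            baseCfg = SceneConfig(), seed = 1L,
                            outDir = NULL, homographyMagnitude = 8,
                            residualMagnitude = 6, fieldSpacing = 16) {
  stopifnot(nTrain >= 0, nFinetune >= 0, nTest >= 0)
  total <- nTrain + nFinetune + nTest
  seeds <- withSeed(seed, matrix(sample.int(2147483646L, 2L * total), ncol = 2L))
  splitOf <- rep(c("train", "finetune", "test"),
                 times = c(nTrain, nFinetune, nTest))
  makePair <- function(i) {
    cfg <- SceneConfig(size = baseCfg@size, nAnimals = baseCfg@nAnimals,
                       floorTextureScale = baseCfg@floorTextureScale,
                       illuminationDelta = baseCfg@illuminationDelta,
                       noiseSd = baseCfg@noiseSd, seed = seeds[i, 1L])
    scene <- generateScene(cfg)
    generateViewPair(scene, homographyMagnitude = homographyMagnitude,
                     residualMagnitude = residualMagnitude,
                     illuminationDelta = baseCfg@illuminationDelta,
                     noiseSd = baseCfg@noiseSd, fieldSpacing = fieldSpacing,
                     seed = seeds[i, 2L])
  }
  pairs <- lapply(seq_len(total), makePair)
  manifest <- data.frame(
    split = splitOf, index = seq_len(total),
    sceneSeed = seeds[, 1L], pairSeed = seeds[, 2L],
    fixedPath = NA_character_, movingPath = NA_character_,
    landmarkPath = NA_character_, stringsAsFactors = FALSE)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(total)) {
      tag <- sprintf("%s_%04d", splitOf[i], i)
      fp <- file.path(outDir, paste0("fixed_", tag, ".png"))
      mp <- file.path(outDir, paste0("moving_", tag, ".png"))
      writeGrayImage(pairs[[i]]@fixed, fp)
      writeGrayImage(pairs[[i]]@movingPrereg, mp)
      manifest$fixedPath[i] <- fp
      manifest$movingPath[i] <- mp
      if (splitOf[i] != "train") {
        lp <- file.path(outDir, paste0("landmarks_", tag, ".csv"))
        writeLandmarksCSV(pairs[[i]]@landmarks, lp, pairId = i)
        manifest$landmarkPath[i] <- lp
      }
    }
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         dataframe = "rows", na = "null", digits = NA)
  }
  new("DatasetSplit",
      train = pairs[splitOf == "train"],
      finetune = pairs[splitOf == "finetune"],
      test = pairs[splitOf == "test"],
      manifest = manifest)
}
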