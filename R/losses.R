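# Similarity metrics, the diffusion regularizer and the composite
# training losses. All metrics operate on [0, 1] grayscale matrices;
# an optional binary mask restricts the averaged pixels (by default the
# losses cover the full frame -- masking is applied to the inputs, not
# the losses).

maskIndices <- function(fixed, mask) {
  if (is.null(mask)) return(NULL)
  if (!is.matrix(mask) || !all(dim(mask) == dim(fixed)))
    stop("mask shape does not match the images")
  idx <- which(mask != 0)
  if (!length(idx)) stop("mask excludes every pixel")
  idx
}

#' Mean-squared-error similarity
#'
#' Mean over included pixels of the squared intensity difference between
#' the fixed image and the warped moving image.
#'
#' @param fixed,warped grayscale matrices of equal shape.
#' @param mask optional binary matrix restricting the average.
#' @return a non-negative scalar.
#' @export
similarityMSE <- function(fixed, warped, mask = NULL) {
  checkGrayImage(fixed, "fixed"); checkGrayImage(warped, "warped")
  if (!all(dim(fixed) == dim(warped))) stop("image shapes differ")
  idx <- maskIndices(fixed, mask)
  d <- fixed - warped
  if (is.null(idx)) mean(d^2) else mean(d[idx]^2)
}

#' Sum-of-squared-differences similarity
#'
#' The unnormalized companion of [similarityMSE()]: the sum (not mean)
#' of squared differences over included pixels, i.e. `n * MSE`.
#'
#' @inheritParams similarityMSE
#' @export
similaritySSD <- function(fixed, warped, mask = NULL) {
  checkGrayImage(fixed, "fixed"); checkGrayImage(warped, "warped")
  if (!all(dim(fixed) == dim(warped))) stop("image shapes differ")
  idx <- maskIndices(fixed, mask)
  d <- fixed - warped
  if (is.null(idx)) sum(d^2) else sum(d[idx]^2)
}

#' Zero-normalized cross-correlation similarity
#'
#' Global zero-normalized cross-correlation in `[-1, 1]`; invariant to
#' affine intensity changes `a * I + b` with `a > 0`, which is what makes
#' it attractive under illumination differences between the two views.
#' Both images must have nonzero variance over the included pixels.
#'
#' @inheritParams similarityMSE
#' @export
similarityNCC <- function(fixed, warped, mask = NULL) {
  checkGrayImage(fixed, "fixed"); checkGrayImage(warped, "warped")
  if (!all(dim(fixed) == dim(warped))) stop("image shapes differ")
  idx <- maskIndices(fixed, mask)
  a <- if (is.null(idx)) as.numeric(fixed) else fixed[idx]
  b <- if (is.null(idx)) as.numeric(warped) else warped[idx]
  ah <- a - mean(a); bh <- b - mean(b)
  sa <- sqrt(sum(ah^2)); sb <- sqrt(sum(bh^2))
  if (sa < 1e-12 || sb < 1e-12)
    stop("NCC is undefined: an image has zero variance over the included pixels")
  sum(ah * bh) / (sa * sb)
}

#' Diffusion regularizer of a displacement field
#'
#' Smoothness penalty: the squared L2 norm of the spatial gradient of the
#' field accumulated over pixels, with gradients taken as forward finite
#' differences in x and y on both displacement channels. Zero iff the
#' field is constant. With `normalize = FALSE` (default) the raw sum is
#' returned; with `normalize = TRUE` the sum is divided by the pixel
#' count, giving the resolution-independent per-pixel mean that the
#' composite training losses combine with `lambda` (the convention of the
#' diffusion-regularized registration literature, under which
#' `lambda = 0.01` is commensurate with a mean-squared-error term on
#' `[0, 1]` intensities).
#'
#' @param field a [DeformationField] or H x W x 2 array (H, W >= 2).
#' @param normalize divide the sum by the number of pixels.
#' @return a non-negative scalar.
#' @export
diffusionRegularizer <- function(field, normalize = FALSE) {
  v <- if (is(field, "DeformationField")) field@vectors else field
  if (length(dim(v)) != 3L || dim(v)[3L] != 2L)
    stop("'field' must be H x W x 2")
  H <- dim(v)[1L]; W <- dim(v)[2L]
  if (H < 2L || W < 2L) stop("field must be at least 2 x 2")
  total <- 0
  for (c in 1:2) {
    u <- v[, , c]
    total <- total + sum((u[, -1L] - u[, -W])^2) +   # d/dx (columns)
      sum((u[-1L, ] - u[-H, ])^2)                    # d/dy (rows)
  }
  if (normalize) total / (H * W) else total
}

# Analytic gradient of diffusionRegularizer w.r.t. the field.
diffusionRegularizerGrad <- function(v, normalize = FALSE) {
  H <- dim(v)[1L]; W <- dim(v)[2L]
  g <- array(0, dim(v))
  for (c in 1:2) {
    u <- v[, , c]
    gx <- u[, -1L] - u[, -W]
    gy <- u[-1L, ] - u[-H, ]
    gu <- matrix(0, H, W)
    gu[, -1L] <- gu[, -1L] + 2 * gx
    gu[, -W] <- gu[, -W] - 2 * gx
    gu[-1L, ] <- gu[-1L, ] + 2 * gy
    gu[-H, ] <- gu[-H, ] - 2 * gy
    g[, , c] <- gu
  }
  if (normalize) g / (H * W) else g
}

similarityValueGrad <- function(fixed, warped, similarity) {
  d <- warped - fixed
  n <- length(d)
  switch(similarity,
    mse = list(value = mean(d^2), grad = 2 * d / n),
    ssd = list(value = sum(d^2), grad = 2 * d),
    ncc = {
      a <- as.numeric(fixed); b <- as.numeric(warped)
      ah <- a - mean(a); bh <- b - mean(b)
      sa <- sqrt(sum(ah^2)); sb <- sqrt(sum(bh^2))
      if (sa < 1e-12 || sb < 1e-12)
        stop("NCC is undefined: an image has zero variance")
      ncc <- sum(ah * bh) / (sa * sb)
      # loss = 1 - NCC (monotone negation of the maximized NCC)
      g <- -(ah / (sa * sb) - ncc * bh / sb^2)
      list(value = 1 - ncc, grad = matrix(g, nrow(fixed), ncol(fixed)))
    },
    stop(sprintf("unknown similarity '%s' (use 'mse', 'ncc' or 'ssd')",
                 similarity)))
}

#' Unsupervised registration loss
#'
#' The training objective of the unsupervised phase: the similarity term
#' between the fixed image and the moving image warped by the field, plus
#' `lambda` times the per-pixel (normalized) diffusion regularizer of the
#' field, so that the two terms stay commensurate at any resolution. NCC
#' enters as the minimized surrogate `1 - NCC`.
#'
#' @param fixed,moving grayscale matrices.
#' @param field a [DeformationField] or H x W x 2 array.
#' @param lambda regularization weight (>= 0).
#' @param similarity `"mse"` (default), `"ncc"` or `"ssd"`.
#' @return a scalar loss value.
#' @export
unsupervisedLoss <- function(fixed, moving, field, lambda = 0.01,
                             similarity = "mse") {
  stopifnot(lambda >= 0)
  warped <- warpImageDense(moving, field)
  sim <- switch(similarity,
    mse = similarityMSE(fixed, warped),
    ssd = similaritySSD(fixed, warped),
    ncc = 1 - similarityNCC(fixed, warped),
    stop(sprintf("unknown similarity '%s' (use 'mse', 'ncc' or 'ssd')",
                 similarity)))
  sim + lambda * diffusionRegularizer(field, normalize = TRUE)
}

# First-order differentiable landmark mapping used during training:
# p' = p - field(p), with the field sampled bilinearly at the moving
# landmark. Returns mapped points plus the per-landmark field samples.
landmarkMapFirstOrder <- function(v, movingPts) {
  phi <- sampleField(v, movingPts)
  list(mapped = movingPts - phi, phi = phi)
}

# Scatter a per-landmark field gradient (n x 2, d/dphi) back onto the
# field array with bilinear weights.
scatterPointGrad <- function(v, movingPts, dphi) {
  g <- array(0, dim(v))
  H <- dim(v)[1L]; W <- dim(v)[2L]
  for (i in seq_len(nrow(movingPts))) {
    x <- movingPts[i, 1L]; y <- movingPts[i, 2L]
    x0 <- floor(x); y0 <- floor(y)
    fx <- x - x0; fy <- y - y0
    for (corner in list(c(y0, x0, (1 - fy) * (1 - fx)),
                        c(y0 + 1, x0, fy * (1 - fx)),
                        c(y0, x0 + 1, (1 - fy) * fx),
                        c(y0 + 1, x0 + 1, fy * fx))) {
      yy <- corner[1L]; xx <- corner[2L]; w <- corner[3L]
      if (yy >= 0 && yy < H && xx >= 0 && xx < W && w != 0) {
        g[yy + 1L, xx + 1L, 1L] <- g[yy + 1L, xx + 1L, 1L] + w * dphi[i, 1L]
        g[yy + 1L, xx + 1L, 2L] <- g[yy + 1L, xx + 1L, 2L] + w * dphi[i, 2L]
      }
    }
  }
  g
}

#' Semi-supervised registration loss
#'
#' The fine-tuning objective: [unsupervisedLoss()] plus `mu` times the
#' mean over landmark pairs of the squared Euclidean distance between the
#' fixed landmarks and the moving landmarks mapped into the fixed frame.
#' During training the mapping uses the differentiable first-order rule
#' `p' = p - field(p)` (the field sampled at the moving landmark), which
#' agrees with the exact inverse used at evaluation time to first order
#' in the field's smoothness.
#'
#' @inheritParams unsupervisedLoss
#' @param landmarks a [PairedLandmarks] (k >= 1 pairs).
#' @param mu landmark-loss weight (>= 0).
#' @return a scalar loss value.
#' @export
semisupervisedLoss <- function(fixed, moving, field, landmarks,
                               lambda = 0.01, mu = 1.0,
                               similarity = "mse") {
  if (is.null(landmarks)) stop("landmark set is required")
  stopifnot(is(landmarks, "PairedLandmarks"), mu >= 0)
  if (length(landmarks) < 1L) stop("at least one landmark pair is required")
  v <- if (is(field, "DeformationField")) field@vectors else field
  base <- unsupervisedLoss(fixed, moving, field, lambda, similarity)
  lm <- landmarkMapFirstOrder(v, landmarks@movingPoints)
  e <- lm$mapped - landmarks@fixedPoints
  base + mu * mean(rowSums(e^2))
}
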