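#' Warp an image with a dense displacement field
#'
#' Backward warping through the spatial-transformer sampling rule: the
#' output at pixel `p = (x, y)` is the bilinear sample of `img` at
#' `p + field(p)`; samples outside the frame fill with 0. With the zero
#' field the image is returned exactly. The operation is differentiable
#' with respect to both the image and the field; the training loop uses
#' the matching adjoint.
#'
#' @param img grayscale image matrix.
#' @param field a [DeformationField] (or H x W x 2 array) of the same
#'   spatial shape.
#' @return the warped image matrix.
#' @export
warpImageDense <- function(img, field) {
  checkGrayImage(img)
  v <- if (is(field, "DeformationField")) field@vectors else field
  if (length(dim(v)) != 3L || !all(dim(v)[1:2] == dim(img)) ||
      dim(v)[3L] != 2L)
    stop(sprintf("field shape (%s) does not match image shape (%d x %d)",
                 paste(dim(v), collapse = " x "), nrow(img), ncol(img)))
  H <- nrow(img); W <- ncol(img)
  dx <- v[, , 1L]; dy <- v[, , 2L]
  if (all(dx == 0) && all(dy == 0)) return(img)
  xs <- matrix(rep(seq_len(W) - 1, each = H), H, W) + dx
  ys <- matrix(rep(seq_len(H) - 1, W), H, W) + dy
  .bilinear_sample(img, xs, ys)
}

# Sample the two field channels at arbitrary (x, y) positions (bilinear).
sampleField <- function(v, points) {
  xs <- matrix(points[, 1L], nrow = 1L)
  ys <- matrix(points[, 2L], nrow = 1L)
  cbind(as.numeric(.bilinear_sample(v[, , 1L], xs, ys)),
        as.numeric(.bilinear_sample(v[, , 2L], xs, ys)))
}

#' Map moving-image landmarks into the fixed frame through a field
#'
#' Inverts the backward image warp for points: the fixed-frame position
#' `p'` of a moving-image landmark `p` satisfies `p' + field(p') = p`
#' (the output pixel `p'` whose sample lands on `p`), solved by an
#' under-relaxed fixed-point iteration
#' `p' <- p' - 0.7 (p' + field(p') - p)` with bilinear field sampling,
#' followed by Newton iterations on the residual (Jacobian
#' `I + grad(field)`) for any landmark the contraction leaves above
#' tolerance -- trained fields can develop local gradients beyond the
#' fixed-point convergence regime while remaining locally invertible.
#' Landmarks lying on a fold of an imperfect field have no exact
#' preimage; the residual-minimizing position is returned as long as the
#' remaining residual stays below `failTol` (sub-pixel best effort,
#' honestly reflected in any TRE computed from it), and a residual above
#' `failTol` raises an error
#' reporting the worst residual. (Training uses the cheaper
#' differentiable first-order approximation `p' = p - field(p)`; see
#' [semisupervisedLoss()].)
#'
#' @param points n x 2 matrix of (x, y) landmarks on the moving image,
#'   inside the frame.
#' @param field a [DeformationField] or H x W x 2 array.
#' @param tol convergence tolerance in pixels.
#' @param maxIter maximum fixed-point iterations.
#' @param failTol residual (pixels) above which non-convergence is an
#'   error.
#' @return n x 2 matrix of fixed-frame landmark positions.
#' @export
warpPointsDense <- function(points, field, tol = 1e-3, maxIter = 30L,
                            failTol = 1) {
  p <- checkPoints(points)
  v <- if (is(field, "DeformationField")) field@vectors else field
  H <- dim(v)[1L]; W <- dim(v)[2L]
  out <- which(p[, 1L] < 0 | p[, 1L] > W - 1 | p[, 2L] < 0 | p[, 2L] > H - 1)
  if (length(out))
    stop(sprintf("landmark %d at (%.2f, %.2f) lies outside the %d x %d frame",
                 out[1L], p[out[1L], 1L], p[out[1L], 2L], H, W))
  q <- p
  omega <- 0.7   # under-relaxation: contractive while |grad(field)| < ~1.8
  for (it in seq_len(maxIter)) {
    resid <- q + sampleField(v, q) - p
    if (max(abs(resid)) < tol) break
    q <- q - omega * resid
  }
  resid <- q + sampleField(v, q) - p
  hard <- which(sqrt(rowSums(resid^2)) >= tol)
  if (length(hard)) {
    # the warp q -> q + field(q) is continuous and proper, so a preimage
    # exists, but it can lie outside the attraction basin of q = p; seed
    # the polish from the best point of a local grid search
    R <- ceiling(max(abs(v))) + 1
    off <- as.matrix(expand.grid(dx = seq(-R, R, by = 0.5),
                                 dy = seq(-R, R, by = 0.5)))
    for (i in hard) {
      cand <- cbind(p[i, 1L] + off[, 1L], p[i, 2L] + off[, 2L])
      r <- cand + sampleField(v, cand) -
        matrix(p[i, ], nrow(cand), 2L, byrow = TRUE)
      q[i, ] <- cand[which.min(rowSums(r^2)), ]
    }
  }
  for (i in hard) {   # Newton on f(q) = q + field(q) - p, 2x2 Jacobian
    qi <- q[i, ]
    for (it in seq_len(20L)) {
      fi <- qi + sampleField(v, matrix(qi, 1L))[1L, ] - p[i, ]
      if (max(abs(fi)) < tol) break
      h <- 0.25
      gx <- (sampleField(v, matrix(qi + c(h, 0), 1L)) -
               sampleField(v, matrix(qi - c(h, 0), 1L)))[1L, ] / (2 * h)
      gy <- (sampleField(v, matrix(qi + c(0, h), 1L)) -
               sampleField(v, matrix(qi - c(0, h), 1L)))[1L, ] / (2 * h)
      J <- diag(2) + cbind(gx, gy)   # d f / d (x, y)
      if (abs(det(J)) < 1e-6) break
      step <- solve(J, fi)
      nrm <- sqrt(sum(step^2))
      if (nrm > 2) step <- step * (2 / nrm)   # trust region: <= 2 px/step
      qi <- qi - step
    }
    q[i, ] <- qi
  }
  resid <- q + sampleField(v, q) - p
  worst <- max(sqrt(rowSums(resid^2)))
  if (worst > failTol)
    stop(sprintf(
      "warpPointsDense did not converge in %d iterations (worst residual %.4g px)",
      maxIter, worst))
  q
}
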