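#' Apply radial lens distortion to points
#'
#' Maps ideal (undistorted) pixel coordinates to their distorted
#' positions. Each point is converted to normalized coordinates
#' `(p - center) / scale`, scaled by the radial factor
#' `1 + k1 r^2 + k2 r^4 + k3 r^6` (with `r` the normalized radius), and
#' converted back to pixels.
#'
#' @param points n x 2 matrix of (x, y) pixel coordinates.
#' @param model a [DistortionModel].
#' @return n x 2 matrix of distorted (x, y) pixel coordinates.
#' @seealso [undistortPoints()], [undistortImage()]
#' @export
distortPoints <- function(points, model) {
  stopifnot(is(model, "DistortionModel"))
  validObject(model)
  p <- checkPoints(points)
  xn <- (p[, 1L] - model@center[1L]) / model@scale
  yn <- (p[, 2L] - model@center[2L]) / model@scale
  r2 <- xn^2 + yn^2
  f <- 1 + model@k1 * r2 + model@k2 * r2^2 + model@k3 * r2^3
  cbind(xn * f * model@scale + model@center[1L],
        yn * f * model@scale + model@center[2L])
}

#' Invert radial lens distortion on points
#'
#' Recovers the ideal coordinates `q` such that
#' `distortPoints(q, model)` reproduces the observed points, by
#' fixed-point iteration on the radial factor:
#' `q_norm <- p_norm / (1 + k1 r^2 + k2 r^4 + k3 r^6)` with `r` taken from
#' the current iterate. Converges whenever the radial polynomial is
#' monotone over the observed radii (small coefficients, in-frame points).
#'
#' @inheritParams distortPoints
#' @param tol convergence tolerance in normalized coordinates.
#' @param maxIter maximum number of fixed-point iterations.
#' @return n x 2 matrix of undistorted (x, y) pixel coordinates.
#' @export
undistortPoints <- function(points, model, tol = 1e-9, maxIter = 20L) {
  stopifnot(is(model, "DistortionModel"))
  validObject(model)
  p <- checkPoints(points)
  xd <- (p[, 1L] - model@center[1L]) / model@scale
  yd <- (p[, 2L] - model@center[2L]) / model@scale
  x <- xd; y <- yd
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    r2 <- x^2 + y^2
    f <- 1 + model@k1 * r2 + model@k2 * r2^2 + model@k3 * r2^3
    if (any(!is.finite(f)) || any(abs(f) < 1e-12)) break
    xn <- xd / f; yn <- yd / f
    delta <- max(abs(xn - x), abs(yn - y))
    x <- xn; y <- yn
    if (delta < tol) { converged <- TRUE; break }
  }
  # residual measured by re-distorting
  r2 <- x^2 + y^2
  f <- 1 + model@k1 * r2 + model@k2 * r2^2 + model@k3 * r2^3
  resid <- pmax(abs(x * f - xd), abs(y * f - yd))
  if (!converged || any(!is.finite(resid)) || max(resid) > sqrt(tol))
    stop(sprintf(
      "undistortPoints did not converge in %d iterations (worst residual %g normalized units); the distortion may not be invertible at these radii",
      maxIter, if (all(is.finite(resid))) max(resid) else Inf))
  cbind(x * model@scale + model@center[1L],
        y * model@scale + model@center[2L])
}

#' Undistort an image
#'
#' Backward resampling: the output intensity at pixel `p` is the bilinear
#' sample of the input at `distortPoints(p, model)`; samples falling
#' outside the frame fill with 0. With zero coefficients the image is
#' returned bit-identically.
#'
#' @param img grayscale image matrix in `[0, 1]`.
#' @param model a [DistortionModel].
#' @return the corrected image matrix.
#' @export
undistortImage <- function(img, model) {
  checkGrayImage(img)
  stopifnot(is(model, "DistortionModel"))
  validObject(model)
  if (model@k1 == 0 && model@k2 == 0 && model@k3 == 0) return(img)
  H <- nrow(img); W <- ncol(img)
  grid <- cbind(rep(seq_len(W) - 1, each = H), rep(seq_len(H) - 1, W))
  d <- distortPoints(grid, model)
  xs <- matrix(d[, 1L], H, W)
  ys <- matrix(d[, 2L], H, W)
  .bilinear_sample(img, xs, ys)
}

#' Mask an image to the pen region
#'
#' Pixels where the mask is 0 are set to 0; pixels inside the pen are
#' unchanged, focusing subsequent registration on the pen content.
#'
#' @param img grayscale image matrix.
#' @param mask binary matrix of the same shape (1 = inside pen); logical
#'   matrices are accepted.
#' @return the masked image.
#' @export
applyMask <- function(img, mask) {
  checkGrayImage(img)
  if (!is.matrix(mask)) stop("'mask' must be a matrix")
  if (!all(dim(mask) == dim(img)))
    stop(sprintf("mask shape (%d x %d) does not match image shape (%d x %d)",
                 nrow(mask), ncol(mask), nrow(img), ncol(img)))
  m <- (mask != 0) * 1
  if (sum(m) == 0) stop("mask excludes every pixel")
  img * m
}

#' Convert an RGB image to grayscale
#'
#' Luma combination with ITU-R BT.601 weights
#' (0.299 R + 0.587 G + 0.114 B); the output range is bounded by the
#' input range.
#'
#' @param rgb H x W x 3 array with channels in `[0, 1]`.
#' @return grayscale image matrix.
#' @export
toGrayscale <- function(rgb) {
  if (length(dim(rgb)) != 3L || dim(rgb)[3L] != 3L)
    stop(sprintf("'rgb' must be an H x W x 3 array (got %s channels)",
                 if (length(dim(rgb)) == 3L) dim(rgb)[3L] else "no"))
  if (any(!is.finite(rgb)) || min(rgb) < 0 || max(rgb) > 1)
    stop("'rgb' intensities must be finite and in [0, 1]")
  0.299 * rgb[, , 1L] + 0.587 * rgb[, , 2L] + 0.114 * rgb[, , 3L]
}

#' Read / write grayscale images
#'
#' PNG (and TIFF, if the `tiff` package is installed) I/O with
#' normalization to `[0, 1]` on load. RGB(A) files are converted with
#' [toGrayscale()] (alpha ignored).
#'
#' @param path file path; format chosen by extension (`.png`, `.tif(f)`).
#' @return `readGrayImage`: a grayscale matrix in `[0, 1]`.
#' @export
readGrayImage <- function(path) {
  ext <- tolower(tools::file_ext(path))
  a <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the 'tiff' package")
    tiff::readTIFF(path)
  } else png::readPNG(path)
  if (length(dim(a)) == 3L) {
    if (dim(a)[3L] >= 3L) a <- toGrayscale(a[, , 1:3, drop = FALSE])
    else a <- a[, , 1L]
  }
  pmin(pmax(a, 0), 1)
}

#' @rdname readGrayImage
#' @param img grayscale matrix in `[0, 1]`.
#' @export
writeGrayImage <- function(img, path) {
  checkGrayImage(img)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("writing TIFF requires the 'tiff' package")
    tiff::writeTIFF(img, path)
  } else png::writePNG(img, path)
  invisible(path)
}

#' Read / write a distortion model as JSON
#'
#' @param path JSON file with fields `k1`, `k2`, optional `k3`, `center`
#'   and `scale`.
#' @return `readDistortionJSON`: a [DistortionModel].
#' @export
readDistortionJSON <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  DistortionModel(k1 = j$k1 %||0% 0, k2 = j$k2 %||0% 0, k3 = j$k3 %||0% 0,
                  center = j$center %||0% c(0, 0), scale = j$scale %||0% 1)
}

`%||0%` <- function(a, b) if (is.null(a)) b else a

#' @rdname readDistortionJSON
#' @param model a [DistortionModel].
#' @export
writeDistortionJSON <- function(model, path) {
  stopifnot(is(model, "DistortionModel"))
  jsonlite::write_json(
    list(k1 = model@k1, k2 = model@k2, k3 = model@k3,
         center = model@center, scale = model@scale),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
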