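#' Fit a projective transform to landmark correspondences
#'
#' Least-squares homography mapping the moving-view points toward the
#' fixed-view points, estimated by the normalized direct linear transform
#' (DLT): both point sets are translated to their centroid and scaled so
#' the mean distance from it is `sqrt(2)`, the 2n x 9 design matrix is
#' solved by SVD for the smallest singular vector, and the normalizations
#' are undone. With four exact correspondences the fit is exact; with more
#' (the pre-registration protocol uses 35 manually placed pairs) the
#' algebraic error is minimized. Landmarks are assumed manual and
#' outlier-free; no robust re-weighting is applied.
#'
#' @param pairs a [PairedLandmarks] with at least 4 pairs.
#' @return a [Homography] mapping moving -> fixed.
#' @export
fitProjective <- function(pairs) {
  stopifnot(is(pairs, "PairedLandmarks"))
  validObject(pairs)
  src <- pairs@movingPoints   # moving -> fixed
  dst <- pairs@fixedPoints
  n <- nrow(src)
  if (n < 4L) stop(sprintf("at least 4 landmark pairs are required (got %d)", n))

  normalise <- function(p) {
    ctr <- colMeans(p)
    d <- sqrt(rowSums(sweep(p, 2L, ctr)^2))
    s <- if (mean(d) > 0) sqrt(2) / mean(d) else 1
    t_mat <- rbind(c(s, 0, -s * ctr[1L]), c(0, s, -s * ctr[2L]), c(0, 0, 1))
    list(T = t_mat, p = cbind(s * (p[, 1L] - ctr[1L]), s * (p[, 2L] - ctr[2L])))
  }
  ns <- normalise(src); nd <- normalise(dst)
  x <- ns$p[, 1L]; y <- ns$p[, 2L]
  u <- nd$p[, 1L]; v <- nd$p[, 2L]
  # rows: [-x -y -1 0 0 0 ux uy u; 0 0 0 -x -y -1 vx vy v]
  A <- matrix(0, 2L * n, 9L)
  A[seq(1L, 2L * n, 2L), ] <- cbind(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
  A[seq(2L, 2L * n, 2L), ] <- cbind(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  sv <- svd(A, nu = 0L, nv = 9L)
  if (sv$d[8L] < 1e-9 * max(sv$d))
    stop("degenerate landmark configuration: design matrix is rank-deficient (are 3 of the points collinear?)")
  h <- matrix(sv$v[, 9L], 3L, 3L, byrow = TRUE)
  h <- solve(nd$T) %*% h %*% ns$T
  if (abs(h[3L, 3L]) < 1e-12)
    stop("degenerate fit: homography cannot be normalized")
  Homography(h)
}

#' Map points through a homography
#'
#' Homogeneous multiplication followed by the perspective divide.
#'
#' @param points n x 2 matrix of (x, y) coordinates.
#' @param h a [Homography].
#' @return n x 2 matrix of mapped coordinates.
#' @export
mapPointsProjective <- function(points, h) {
  stopifnot(is(h, "Homography"))
  p <- checkPoints(points)
  m <- h@matrix
  ph <- cbind(p, 1) %*% t(m)
  w <- ph[, 3L]
  bad <- which(abs(w) < 1e-12)
  if (length(bad))
    stop(sprintf("point %d maps to the plane at infinity (w = %g)",
                 bad[1L], w[bad[1L]]))
  cbind(ph[, 1L] / w, ph[, 2L] / w)
}

#' Inverse of a homography
#' @param h a [Homography].
#' @return the inverse [Homography].
#' @export
invertHomography <- function(h) {
  stopifnot(is(h, "Homography"))
  Homography(solve(h@matrix))
}

#' Warp an image by a projective transform
#'
#' Backward warping: the output pixel at `p` is the bilinear sample of the
#' input at `h^{-1}(p)`, so that image content moves the way
#' [mapPointsProjective()] moves points. Out-of-frame samples fill with 0.
#'
#' @param img grayscale image matrix.
#' @param h a [Homography] (the moving -> fixed map used on points).
#' @return the warped image, same shape as `img`.
#' @export
warpImageProjective <- function(img, h) {
  checkGrayImage(img)
  stopifnot(is(h, "Homography"))
  hinv <- tryCatch(solve(h@matrix),
                   error = function(e) stop("homography is singular"))
  H <- nrow(img); W <- ncol(img)
  grid <- cbind(rep(seq_len(W) - 1, each = H), rep(seq_len(H) - 1, W))
  src <- mapPointsProjective(grid, Homography(hinv))
  xs <- matrix(src[, 1L], H, W)
  ys <- matrix(src[, 2L], H, W)
  .bilinear_sample(img, xs, ys)
}

#' Read / write a homography as JSON (3 x 3 row-major array)
#'
#' @param path JSON file path.
#' @return `readHomographyJSON`: a [Homography].
#' @export
readHomographyJSON <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.list(m)) m <- do.call(rbind, m)
  Homography(m)
}

#' @rdname readHomographyJSON
#' @param h a [Homography].
#' @export
writeHomographyJSON <- function(h, path) {
  stopifnot(is(h, "Homography"))
  jsonlite::write_json(
    lapply(seq_len(3L), function(i) h@matrix[i, ]),
    path, digits = NA)
  invisible(path)
}
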