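# U-Net style displacement-field network.
#
# The network maps the stacked (fixed, moving) 2-channel image to an
# H x W x 2 displacement field. Architecture per level: two 3x3 "same"
# convolutions with (leaky) ReLU; 2x2 max pooling between encoder levels;
# 2x2 transposed-convolution upsampling; skip concatenation of the encoder
# feature map (instance-normalized when enabled); final 1x1 convolution
# with two kernels. Forward and backward passes are written against the
# BLAS-backed kernels in src/ops.cpp; the backward pass is an exact
# reverse-mode differentiation of the forward graph (verified against
# finite differences in the test suite).

actForward <- function(x, config) {
  slope <- if (config@activation == "relu") 0 else config@actSlope
  x * ((x > 0) + slope * (x <= 0))
}

actBackward <- function(pre, grad, config) {
  slope <- if (config@activation == "relu") 0 else config@actSlope
  grad * ((pre > 0) + slope * (pre <= 0))
}

instNormForward <- function(x, eps = 1e-5) {
  C <- dim(x)[3L]
  y <- x; mu <- numeric(C); sigma <- numeric(C)
  for (c in seq_len(C)) {
    xc <- x[, , c]
    mu[c] <- mean(xc)
    sigma[c] <- sqrt(mean((xc - mu[c])^2) + eps)
    y[, , c] <- (xc - mu[c]) / sigma[c]
  }
  list(y = y, mu = mu, sigma = sigma)
}

instNormBackward <- function(cache, dy) {
  C <- dim(dy)[3L]
  dx <- dy
  for (c in seq_len(C)) {
    g <- dy[, , c]; yc <- cache$y[, , c]
    dx[, , c] <- (g - mean(g) - yc * mean(g * yc)) / cache$sigma[c]
  }
  dx
}

# Parameter template: names and shapes fully determined by the config.
thetaShapes <- function(config) {
  L <- config@levels; f <- config@filtersPerLevel; K <- config@kernelSize
  shapes <- list()
  cin <- 2L
  for (l in seq_len(L - 1L)) {
    shapes[[sprintf("enc%da_w", l)]] <- c(K * K * cin, f[l])
    shapes[[sprintf("enc%da_b", l)]] <- f[l]
    shapes[[sprintf("enc%db_w", l)]] <- c(K * K * f[l], f[l])
    shapes[[sprintf("enc%db_b", l)]] <- f[l]
    cin <- f[l]
  }
  shapes[["bot_a_w"]] <- c(K * K * f[L - 1L], f[L])
  shapes[["bot_a_b"]] <- f[L]
  shapes[["bot_b_w"]] <- c(K * K * f[L], f[L])
  shapes[["bot_b_b"]] <- f[L]
  for (l in rev(seq_len(L - 1L))) {
    shapes[[sprintf("up%d_w", l)]] <- c(4L * f[l + 1L], f[l])
    shapes[[sprintf("up%d_b", l)]] <- f[l]
    shapes[[sprintf("dec%da_w", l)]] <- c(K * K * 2L * f[l], f[l])
    shapes[[sprintf("dec%da_b", l)]] <- f[l]
    shapes[[sprintf("dec%db_w", l)]] <- c(K * K * f[l], f[l])
    shapes[[sprintf("dec%db_b", l)]] <- f[l]
  }
  shapes[["out_w"]] <- c(config@filtersPerLevel[1L], 2L)
  shapes[["out_b"]] <- 2L
  shapes
}

#' Build a displacement-field registration network
#'
#' Instantiates the encoder--decoder described by `config` with
#' He (Kaiming) initialized weights: each weight matrix is drawn from
#' `N(0, 2 / ((1 + slope^2) * fan_in))` with `fan_in` the number of input
#' connections per kernel; biases start at zero. The final 1 x 1 flow
#' layer is initialized near zero (SD 1e-3, the usual convention for
#' displacement-field networks) so the untrained model predicts an
#' almost-identity warp rather than a large random deformation. The same
#' `seed` and `config` always produce bit-identical initial parameters.
#'
#' @param config a [NetworkConfig].
#' @param seed integer RNG seed for the initialization.
#' @return an untrained [RegistrationModel].
#' @export
buildNetwork <- function(config, seed = 1L) {
  stopifnot(is(config, "NetworkConfig"))
  validObject(config)
  slope <- if (config@activation == "relu") 0 else config@actSlope
  shapes <- thetaShapes(config)
  theta <- withSeed(seed, {
    out <- lapply(shapes, function(shp) {
      if (length(shp) == 1L) numeric(shp)  # bias
      else {
        fan_in <- shp[1L]
        sd <- sqrt(2 / ((1 + slope^2) * fan_in))
        matrix(rnorm(prod(shp), sd = sd), shp[1L], shp[2L])
      }
    })
    # near-zero flow head: start from the identity warp
    out[["out_w"]] <- matrix(rnorm(prod(shapes[["out_w"]]), sd = 1e-3),
                             shapes[["out_w"]][1L], shapes[["out_w"]][2L])
    out
  })
  new("RegistrationModel", config = config, theta = theta,
      trainingPhase = "untrained",
      history = data.frame(epoch = integer(), loss = numeric(),
                           lr = numeric(), phase = character()))
}

# Forward pass. Returns list(field = H x W x 2 array, cache = list or NULL).
netForward <- function(theta, config, fixed, moving, keepCache = FALSE) {
  H <- config@inputSize[1L]; W <- config@inputSize[2L]
  if (nrow(fixed) != H || ncol(fixed) != W ||
      nrow(moving) != H || ncol(moving) != W)
    stop(sprintf(
      "image shape (%d x %d) does not match the network input size (%d x %d)",
      nrow(fixed), ncol(fixed), H, W))
  L <- config@levels; K <- config@kernelSize
  cache <- if (keepCache) list(enc = vector("list", L - 1L),
                               dec = vector("list", L - 1L)) else NULL
  x <- array(c(fixed, moving), c(H, W, 2L))
  skips <- vector("list", L - 1L)
  for (l in seq_len(L - 1L)) {
    a1pre <- .conv2d_fw(x, theta[[sprintf("enc%da_w", l)]],
                        theta[[sprintf("enc%da_b", l)]], K)
    a1 <- actForward(a1pre, config)
    a2pre <- .conv2d_fw(a1, theta[[sprintf("enc%db_w", l)]],
                        theta[[sprintf("enc%db_b", l)]], K)
    if (config@residualBlocks) a2pre <- a2pre + a1
    a2 <- actForward(a2pre, config)
    pool <- .maxpool2_fw(a2)
    if (keepCache)
      cache$enc[[l]] <- list(x = x, a1pre = a1pre, a1 = a1, a2pre = a2pre,
                             poolidx = pool$idx, hw = dim(a2)[1:2])
    skips[[l]] <- a2
    x <- pool$Y
  }
  b1pre <- .conv2d_fw(x, theta[["bot_a_w"]], theta[["bot_a_b"]], K)
  b1 <- actForward(b1pre, config)
  b2pre <- .conv2d_fw(b1, theta[["bot_b_w"]], theta[["bot_b_b"]], K)
  if (config@residualBlocks) b2pre <- b2pre + b1
  h <- actForward(b2pre, config)
  if (keepCache)
    cache$bot <- list(x = x, a1pre = b1pre, a1 = b1, a2pre = b2pre)
  for (l in rev(seq_len(L - 1L))) {
    up <- .deconv2_fw(h, theta[[sprintf("up%d_w", l)]],
                      theta[[sprintf("up%d_b", l)]])
    s <- skips[[l]]
    instCache <- NULL
    if (config@useInstanceNorm) {
      instCache <- instNormForward(s)
      s <- instCache$y
    }
    cs <- dim(s)[3L]
    cat_ <- array(0, c(dim(s)[1L], dim(s)[2L], cs + dim(up)[3L]))
    cat_[, , seq_len(cs)] <- s
    cat_[, , cs + seq_len(dim(up)[3L])] <- up
    d1pre <- .conv2d_fw(cat_, theta[[sprintf("dec%da_w", l)]],
                        theta[[sprintf("dec%da_b", l)]], K)
    d1 <- actForward(d1pre, config)
    d2pre <- .conv2d_fw(d1, theta[[sprintf("dec%db_w", l)]],
                        theta[[sprintf("dec%db_b", l)]], K)
    if (config@residualBlocks) d2pre <- d2pre + d1
    d2 <- actForward(d2pre, config)
    if (keepCache)
      cache$dec[[l]] <- list(hin = h, cat = cat_, inst = instCache,
                             nskip = cs, d1pre = d1pre, d1 = d1,
                             d2pre = d2pre)
    h <- d2
  }
  field <- .conv2d_fw(h, theta[["out_w"]], theta[["out_b"]], 1L)
  clampMask <- NULL
  if (is.finite(config@fieldClamp)) {
    clampMask <- abs(field) < config@fieldClamp
    field <- pmin(pmax(field, -config@fieldClamp), config@fieldClamp)
  }
  if (keepCache) {
    cache$outIn <- h
    cache$clampMask <- clampMask
  }
  list(field = field, cache = cache)
}

# Reverse-mode gradient of the forward pass: dfield (H x W x 2) in,
# named list of parameter gradients out.
netBackward <- function(theta, config, cache, dfield) {
  L <- config@levels; K <- config@kernelSize
  grads <- list()
  if (!is.null(cache$clampMask)) dfield <- dfield * cache$clampMask
  bw <- .conv2d_bw(cache$outIn, theta[["out_w"]], dfield, 1L)
  grads[["out_w"]] <- bw$dW; grads[["out_b"]] <- bw$db
  dh <- bw$dX
  for (l in seq_len(L - 1L)) {   # decoder levels, innermost-last in forward
    dc <- cache$dec[[l]]
    dd2pre <- actBackward(dc$d2pre, dh, config)
    bw <- .conv2d_bw(dc$d1, theta[[sprintf("dec%db_w", l)]], dd2pre, K)
    grads[[sprintf("dec%db_w", l)]] <- bw$dW
    grads[[sprintf("dec%db_b", l)]] <- bw$db
    dd1 <- bw$dX
    if (config@residualBlocks) dd1 <- dd1 + dd2pre
    dd1pre <- actBackward(dc$d1pre, dd1, config)
    bw <- .conv2d_bw(dc$cat, theta[[sprintf("dec%da_w", l)]], dd1pre, K)
    grads[[sprintf("dec%da_w", l)]] <- bw$dW
    grads[[sprintf("dec%da_b", l)]] <- bw$db
    dcat <- bw$dX
    cs <- dc$nskip
    dskip <- dcat[, , seq_len(cs), drop = FALSE]
    dup <- dcat[, , cs + seq_len(dim(dcat)[3L] - cs), drop = FALSE]
    if (config@useInstanceNorm) dskip <- instNormBackward(dc$inst, dskip)
    # store skip gradient for the encoder sweep below
    cache$dec[[l]]$dskip <- dskip
    bw <- .deconv2_bw(dc$hin, theta[[sprintf("up%d_w", l)]], dup)
    grads[[sprintf("up%d_w", l)]] <- bw$dW
    grads[[sprintf("up%d_b", l)]] <- bw$db
    dh <- bw$dX
  }
  # bottleneck
  bc <- cache$bot
  db2pre <- actBackward(bc$a2pre, dh, config)
  bw <- .conv2d_bw(bc$a1, theta[["bot_b_w"]], db2pre, K)
  grads[["bot_b_w"]] <- bw$dW; grads[["bot_b_b"]] <- bw$db
  db1 <- bw$dX
  if (config@residualBlocks) db1 <- db1 + db2pre
  db1pre <- actBackward(bc$a1pre, db1, config)
  bw <- .conv2d_bw(bc$x, theta[["bot_a_w"]], db1pre, K)
  grads[["bot_a_w"]] <- bw$dW; grads[["bot_a_b"]] <- bw$db
  dpool <- bw$dX
  # encoder, deepest level first
  for (l in rev(seq_len(L - 1L))) {
    ec <- cache$enc[[l]]
    da2 <- .maxpool2_bw(dpool, ec$poolidx, ec$hw[1L], ec$hw[2L])
    da2 <- da2 + cache$dec[[l]]$dskip     # skip-connection path
    da2pre <- actBackward(ec$a2pre, da2, config)
    bw <- .conv2d_bw(ec$a1, theta[[sprintf("enc%db_w", l)]], da2pre, K)
    grads[[sprintf("enc%db_w", l)]] <- bw$dW
    grads[[sprintf("enc%db_b", l)]] <- bw$db
    da1 <- bw$dX
    if (config@residualBlocks) da1 <- da1 + da2pre
    da1pre <- actBackward(ec$a1pre, da1, config)
    bw <- .conv2d_bw(ec$x, theta[[sprintf("enc%da_w", l)]], da1pre, K)
    grads[[sprintf("enc%da_w", l)]] <- bw$dW
    grads[[sprintf("enc%da_b", l)]] <- bw$db
    dpool <- bw$dX
  }
  # arma::vec results surface as n x 1 matrices; biases are plain vectors
  for (nm in names(grads))
    if (endsWith(nm, "_b")) grads[[nm]] <- as.numeric(grads[[nm]])
  grads
}

#' Predict the displacement field for an image pair
#'
#' One deterministic forward pass of the network on the stacked
#' (fixed, moving) input; no stochastic layers are involved, so repeated
#' calls with the same parameters return identical fields.
#'
#' @param model a [RegistrationModel].
#' @param fixed,moving grayscale image matrices matching the configured
#'   input size.
#' @return a [DeformationField] (backward-warp convention).
#' @export
predictField <- function(model, fixed, moving) {
  stopifnot(is(model, "RegistrationModel"))
  checkGrayImage(fixed, "fixed"); checkGrayImage(moving, "moving")
  out <- netForward(model@theta, model@config, fixed, moving)
  DeformationField(out$field)
}
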