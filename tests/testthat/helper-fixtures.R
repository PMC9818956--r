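# Shared fixtures: all built in code, sized for speed.

randImage <- function(H = 16, W = H, seed = 1) {
  set.seed(seed)
  matrix(runif(H * W), H, W)
}

toyConfig <- function(H = 16, W = H, levels = 2, filters = c(4, 6), ...) {
  NetworkConfig(levels = levels, filtersPerLevel = filters,
                inputSize = c(H, W), ...)
}

constantField <- function(H, W, dx, dy) {
  DeformationField(array(c(matrix(dx, H, W), matrix(dy, H, W)),
                         c(H, W, 2L)))
}

# Model with a generically scaled flow head for gradient checks: the
# default near-zero output layer makes upstream gradients so small that
# finite differences drown in rounding noise.
gradCheckModel <- function(cfg, seed) {
  m <- buildNetwork(cfg, seed = seed)
  set.seed(seed + 1000)
  m@theta[["out_w"]][] <- rnorm(length(m@theta[["out_w"]]), sd = 0.5)
  m
}

# A numerically independent double-loop evaluation of the diffusion
# regularizer (forward differences, sum of squared gradient norms).
diffusionOracle <- function(v) {
  H <- dim(v)[1L]; W <- dim(v)[2L]
  total <- 0
  for (c in 1:2)
    for (i in seq_len(H))
      for (j in seq_len(W)) {
        if (j < W) total <- total + (v[i, j + 1, c] - v[i, j, c])^2
        if (i < H) total <- total + (v[i + 1, j, c] - v[i, j, c])^2
      }
  total
}

# Scalar re-implementation of the radial distortion polynomial.
distortOracle <- function(p, k1, k2, k3, center, scale) {
  xn <- (p[1] - center[1]) / scale
  yn <- (p[2] - center[2]) / scale
  r2 <- xn^2 + yn^2
  f <- 1 + k1 * r2 + k2 * r2^2 + k3 * r2^3
  c(xn * f * scale + center[1], yn * f * scale + center[2])
}
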