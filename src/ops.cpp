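// Low-level numeric kernels for the displacement-field network and warps.
//
// Conventions shared with the R code:
//   * feature maps are H x W x C cubes (R arrays, column-major);
//   * conv weights are (K*K*Cin) x Cout matrices, column index of an input
//     patch element = ki + K*kj + K*K*c (ki = row offset, kj = col offset);
//   * point coordinates are 0-based with x = column, y = row, pixel centers
//     at integer coordinates;
//   * bilinear samples outside the frame contribute zero (zero fill).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// im2col for "same" zero padding, odd kernel size K.
// Returns (H*W) x (K*K*Cin); row index = i + H*j (pixel order matches
// column-major flattening of an H x W map).
static arma::mat im2col_same(const arma::cube& X, const int K) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  const int pad = (K - 1) / 2;
  arma::mat cols(static_cast<size_t>(H) * W, static_cast<size_t>(K) * K * C,
                 arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const arma::mat& Xc = X.slice(c);
    for (int kj = 0; kj < K; ++kj) {
      for (int ki = 0; ki < K; ++ki) {
        const int col_idx = ki + K * kj + K * K * c;
        // source pixel (i + ki - pad, j + kj - pad)
        const int di = ki - pad, dj = kj - pad;
        const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
        const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
        if (i0 >= i1 || j0 >= j1) continue;
        for (int j = j0; j < j1; ++j) {
          double* dst = cols.colptr(col_idx) + static_cast<size_t>(H) * j + i0;
          const double* src = Xc.colptr(j + dj) + (i0 + di);
          std::copy(src, src + (i1 - i0), dst);
        }
      }
    }
  }
  return cols;
}

// Adjoint of im2col_same: scatter (H*W) x (K*K*Cin) back onto H x W x Cin.
static arma::cube col2im_same(const arma::mat& cols, const int H, const int W,
                              const int C, const int K) {
  const int pad = (K - 1) / 2;
  arma::cube X(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    arma::mat& Xc = X.slice(c);
    for (int kj = 0; kj < K; ++kj) {
      for (int ki = 0; ki < K; ++ki) {
        const int col_idx = ki + K * kj + K * K * c;
        const int di = ki - pad, dj = kj - pad;
        const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
        const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
        if (i0 >= i1 || j0 >= j1) continue;
        for (int j = j0; j < j1; ++j) {
          const double* src = cols.colptr(col_idx) + static_cast<size_t>(H) * j + i0;
          double* dst = Xc.colptr(j + dj) + (i0 + di);
          for (int i = 0; i < i1 - i0; ++i) dst[i] += src[i];
        }
      }
    }
  }
  return X;
}

// [[Rcpp::export(name = ".conv2d_fw")]]
arma::cube conv2d_fw(const arma::cube& X, const arma::mat& W,
                     const arma::vec& b, const int K) {
  const int H = X.n_rows, Wd = X.n_cols;
  const int Cout = W.n_cols;
  arma::mat cols = im2col_same(X, K);
  arma::mat Y = cols * W;            // (H*W) x Cout
  Y.each_row() += b.t();
  arma::cube out(H, Wd, Cout);
  std::copy(Y.memptr(), Y.memptr() + Y.n_elem, out.memptr());
  return out;
}

// [[Rcpp::export(name = ".conv2d_bw")]]
List conv2d_bw(const arma::cube& X, const arma::mat& W, const arma::cube& dY,
               const int K) {
  const int H = X.n_rows, Wd = X.n_cols, Cin = X.n_slices;
  const int Cout = dY.n_slices;
  arma::mat cols = im2col_same(X, K);
  arma::mat dYm(const_cast<double*>(dY.memptr()),
                static_cast<size_t>(H) * Wd, Cout, false, true);
  arma::mat dW = cols.t() * dYm;
  arma::vec db = arma::sum(dYm, 0).t();
  arma::mat dcols = dYm * W.t();
  arma::cube dX = col2im_same(dcols, H, Wd, Cin, K);
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// 2x2 max pooling, stride 2. Returns pooled map and flat argmax indices
// (0-based into the input slice) for the backward pass.
// [[Rcpp::export(name = ".maxpool2_fw")]]
List maxpool2_fw(const arma::cube& X) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  arma::cube Y(Ho, Wo, C);
  arma::ucube idx(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    const arma::mat& Xc = X.slice(c);
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        const int i2 = 2 * i, j2 = 2 * j;
        double best = Xc(i2, j2);
        int bi = i2, bj = j2;
        if (Xc(i2 + 1, j2) > best) { best = Xc(i2 + 1, j2); bi = i2 + 1; }
        if (Xc(i2, j2 + 1) > best) { best = Xc(i2, j2 + 1); bi = i2; bj = j2 + 1; }
        if (Xc(i2 + 1, j2 + 1) > best) { best = Xc(i2 + 1, j2 + 1); bi = i2 + 1; bj = j2 + 1; }
        Y(i, j, c) = best;
        idx(i, j, c) = static_cast<arma::uword>(bi) + static_cast<arma::uword>(H) * bj;
      }
    }
  }
  return List::create(_["Y"] = Y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_bw")]]
arma::cube maxpool2_bw(const arma::cube& dY, const arma::ucube& idx,
                       const int H, const int W) {
  const int Ho = dY.n_rows, Wo = dY.n_cols, C = dY.n_slices;
  arma::cube dX(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    arma::mat& dXc = dX.slice(c);
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i)
        dXc(idx(i, j, c)) += dY(i, j, c);
  }
  return dX;
}

// Transposed convolution, 2x2 kernel, stride 2 (doubles H and W).
// Weight layout: (4*Cin) x Cout, rows blocked by offset o = ki + 2*kj
// (ki, kj in {0,1}), i.e. rows [o*Cin, (o+1)*Cin) hold the Cin x Cout
// map for output position (2i+ki, 2j+kj).
// [[Rcpp::export(name = ".deconv2_fw")]]
arma::cube deconv2_fw(const arma::cube& X, const arma::mat& W,
                      const arma::vec& b) {
  const int h = X.n_rows, w = X.n_cols, Cin = X.n_slices;
  const int Cout = W.n_cols;
  arma::mat Xm(const_cast<double*>(X.memptr()),
               static_cast<size_t>(h) * w, Cin, false, true);
  arma::cube Y(2 * h, 2 * w, Cout);
  for (int o = 0; o < 4; ++o) {
    const int ki = o % 2, kj = o / 2;
    arma::mat Yo = Xm * W.rows(o * Cin, (o + 1) * Cin - 1);  // (h*w) x Cout
    Yo.each_row() += b.t();   // offsets tile the output: one bias add per output pixel
    for (int c = 0; c < Cout; ++c) {
      const double* src = Yo.colptr(c);
      arma::mat& Yc = Y.slice(c);
      for (int j = 0; j < w; ++j)
        for (int i = 0; i < h; ++i)
          Yc(2 * i + ki, 2 * j + kj) = src[i + static_cast<size_t>(h) * j];
    }
  }
  return Y;
}

// [[Rcpp::export(name = ".deconv2_bw")]]
List deconv2_bw(const arma::cube& X, const arma::mat& W, const arma::cube& dY) {
  const int h = X.n_rows, w = X.n_cols, Cin = X.n_slices;
  const int Cout = dY.n_slices;
  arma::mat Xm(const_cast<double*>(X.memptr()),
               static_cast<size_t>(h) * w, Cin, false, true);
  arma::mat dW(4 * Cin, Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::mat dXm(static_cast<size_t>(h) * w, Cin, arma::fill::zeros);
  arma::mat dYo(static_cast<size_t>(h) * w, Cout);
  for (int o = 0; o < 4; ++o) {
    const int ki = o % 2, kj = o / 2;
    for (int c = 0; c < Cout; ++c) {
      double* dst = dYo.colptr(c);
      const arma::mat& dYc = dY.slice(c);
      for (int j = 0; j < w; ++j)
        for (int i = 0; i < h; ++i)
          dst[i + static_cast<size_t>(h) * j] = dYc(2 * i + ki, 2 * j + kj);
    }
    dW.rows(o * Cin, (o + 1) * Cin - 1) = Xm.t() * dYo;
    db += arma::sum(dYo, 0).t();
    dXm += dYo * W.rows(o * Cin, (o + 1) * Cin - 1).t();
  }
  arma::cube dX(h, w, Cin);
  std::copy(dXm.memptr(), dXm.memptr() + dXm.n_elem, dX.memptr());
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// Bilinear sample img at (xs, ys) grids (0-based coords); corners falling
// outside the frame contribute zero, so fully out-of-frame samples are 0.
// [[Rcpp::export(name = ".bilinear_sample")]]
arma::mat bilinear_sample(const arma::mat& img, const arma::mat& xs,
                          const arma::mat& ys) {
  const int H = img.n_rows, W = img.n_cols;
  const int Ho = xs.n_rows, Wo = xs.n_cols;
  arma::mat out(Ho, Wo, arma::fill::zeros);
  for (int j = 0; j < Wo; ++j) {
    for (int i = 0; i < Ho; ++i) {
      const double x = xs(i, j), y = ys(i, j);
      const int x0 = static_cast<int>(std::floor(x));
      const int y0 = static_cast<int>(std::floor(y));
      const double fx = x - x0, fy = y - y0;
      double v = 0.0;
      if (y0 >= 0 && y0 < H && x0 >= 0 && x0 < W)
        v += (1 - fy) * (1 - fx) * img(y0, x0);
      if (y0 + 1 >= 0 && y0 + 1 < H && x0 >= 0 && x0 < W)
        v += fy * (1 - fx) * img(y0 + 1, x0);
      if (y0 >= 0 && y0 < H && x0 + 1 >= 0 && x0 + 1 < W)
        v += (1 - fy) * fx * img(y0, x0 + 1);
      if (y0 + 1 >= 0 && y0 + 1 < H && x0 + 1 >= 0 && x0 + 1 < W)
        v += fy * fx * img(y0 + 1, x0 + 1);
      out(i, j) = v;
    }
  }
  return out;
}

// Backward of out(i,j) = bilinear(img, j + dx(i,j), i + dy(i,j)):
// gradients w.r.t. img (scatter) and w.r.t. dx, dy (spatial derivative of
// the bilinear kernel). Mirrors the spatial-transformer sampling layer.
// [[Rcpp::export(name = ".warp_bilinear_bw")]]
List warp_bilinear_bw(const arma::mat& img, const arma::mat& dx,
                      const arma::mat& dy, const arma::mat& dout) {
  const int H = img.n_rows, W = img.n_cols;
  arma::mat dimg(H, W, arma::fill::zeros);
  arma::mat ddx(H, W, arma::fill::zeros);
  arma::mat ddy(H, W, arma::fill::zeros);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      const double g = dout(i, j);
      if (g == 0.0) continue;
      const double x = j + dx(i, j), y = i + dy(i, j);
      const int x0 = static_cast<int>(std::floor(x));
      const int y0 = static_cast<int>(std::floor(y));
      const double fx = x - x0, fy = y - y0;
      double v00 = 0, v10 = 0, v01 = 0, v11 = 0;
      const bool in00 = (y0 >= 0 && y0 < H && x0 >= 0 && x0 < W);
      const bool in10 = (y0 + 1 >= 0 && y0 + 1 < H && x0 >= 0 && x0 < W);
      const bool in01 = (y0 >= 0 && y0 < H && x0 + 1 >= 0 && x0 + 1 < W);
      const bool in11 = (y0 + 1 >= 0 && y0 + 1 < H && x0 + 1 >= 0 && x0 + 1 < W);
      if (in00) { v00 = img(y0, x0); dimg(y0, x0) += g * (1 - fy) * (1 - fx); }
      if (in10) { v10 = img(y0 + 1, x0); dimg(y0 + 1, x0) += g * fy * (1 - fx); }
      if (in01) { v01 = img(y0, x0 + 1); dimg(y0, x0 + 1) += g * (1 - fy) * fx; }
      if (in11) { v11 = img(y0 + 1, x0 + 1); dimg(y0 + 1, x0 + 1) += g * fy * fx; }
      // d value / d x and d value / d y of the bilinear interpolant
      ddx(i, j) = g * ((1 - fy) * (v01 - v00) + fy * (v11 - v10));
      ddy(i, j) = g * ((1 - fx) * (v10 - v00) + fx * (v11 - v01));
    }
  }
  return List::create(_["dimg"] = dimg, _["ddx"] = ddx, _["ddy"] = ddy);
}
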