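// Compute kernels for the tiny CNN and image augmentation.
//
// Activation arrays are column-major (N, H, W, C), matching R's layout.
// Convolutions are 3x3, stride 1, zero same-padding, realized as an
// im2col gather followed by one GEMM; kernel offsets (di, dj) in {0,1,2}^2
// are enumerated row-major with input channels fastest, matching the
// (9 * C_in, C_out) weight layout on the R side.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::uword idx4(arma::uword n, arma::uword h, arma::uword w,
                               arma::uword c, arma::uword N, arma::uword H,
                               arma::uword W) {
  return n + N * (h + H * (w + W * c));
}

// [[Rcpp::export]]
List cpp_conv_forward(const arma::vec& x, IntegerVector dims,
                      const arma::mat& W, const arma::vec& b, bool relu) {
  const arma::uword N = dims[0], H = dims[1], Wd = dims[2], C = dims[3];
  const arma::uword rows = N * H * Wd;
  arma::mat col(rows, 9 * C, arma::fill::zeros);
  for (arma::uword k = 0; k < 9; ++k) {
    const int di = (int)(k / 3) - 1, dj = (int)(k % 3) - 1;
    for (arma::uword c = 0; c < C; ++c) {
      double* dst = col.colptr(k * C + c);
      for (arma::uword w = 0; w < Wd; ++w) {
        const int ws = (int)w + dj;
        if (ws < 0 || ws >= (int)Wd) continue;
        for (arma::uword h = 0; h < H; ++h) {
          const int hs = (int)h + di;
          if (hs < 0 || hs >= (int)H) continue;
          const double* src = x.memptr() + idx4(0, hs, ws, c, N, H, Wd);
          double* out = dst + N * (h + H * w);
          std::copy(src, src + N, out);
        }
      }
    }
  }
  arma::mat y = col * W;
  y.each_row() += b.t();
  if (relu) y.transform([](double v) { return v > 0 ? v : 0.0; });
  return List::create(_["out"] = y, _["col"] = col);
}

// Backward through (fused) conv + ReLU: `out` is the rectified forward
// output; the incoming gradient is masked by out > 0 before the GEMMs.
// [[Rcpp::export]]
List cpp_conv_backward(const arma::mat& dout_in, IntegerVector in_dims,
                       const arma::mat& col, const arma::mat& W,
                       const arma::vec& out, bool relu, bool need_dx) {
  const arma::uword N = in_dims[0], H = in_dims[1], Wd = in_dims[2],
                    C = in_dims[3];
  arma::mat dout_mat = dout_in;
  if (relu) {
    double* d = dout_mat.memptr();
    const double* o = out.memptr();
    for (arma::uword i = 0; i < dout_mat.n_elem; ++i)
      if (o[i] <= 0) d[i] = 0.0;
  }
  arma::mat dW = col.t() * dout_mat;
  arma::rowvec db = arma::sum(dout_mat, 0);
  if (!need_dx) {
    return List::create(_["dW"] = dW, _["db"] = db, _["dx"] = R_NilValue);
  }
  arma::mat dcol = dout_mat * W.t();
  arma::vec dx(N * H * Wd * C, arma::fill::zeros);
  for (arma::uword k = 0; k < 9; ++k) {
    const int di = (int)(k / 3) - 1, dj = (int)(k % 3) - 1;
    for (arma::uword c = 0; c < C; ++c) {
      const double* src0 = dcol.colptr(k * C + c);
      for (arma::uword w = 0; w < Wd; ++w) {
        const int ws = (int)w + dj;
        if (ws < 0 || ws >= (int)Wd) continue;
        for (arma::uword h = 0; h < H; ++h) {
          const int hs = (int)h + di;
          if (hs < 0 || hs >= (int)H) continue;
          double* dst = dx.memptr() + idx4(0, hs, ws, c, N, H, Wd);
          const double* src = src0 + N * (h + H * w);
          for (arma::uword n = 0; n < N; ++n) dst[n] += src[n];
        }
      }
    }
  }
  return List::create(_["dW"] = dW, _["db"] = db, _["dx"] = dx);
}

// 2x2 max pooling, stride 2. Returns pooled values and the winning
// quadrant (1..4, first occurrence wins ties) for the backward pass.
// [[Rcpp::export]]
List cpp_maxpool_forward(const arma::vec& x, IntegerVector dims) {
  const arma::uword N = dims[0], H = dims[1], W = dims[2], C = dims[3];
  const arma::uword Ho = H / 2, Wo = W / 2;
  arma::vec out(N * Ho * Wo * C);
  IntegerVector arg(N * Ho * Wo * C);
  for (arma::uword c = 0; c < C; ++c)
    for (arma::uword w = 0; w < Wo; ++w)
      for (arma::uword h = 0; h < Ho; ++h)
        for (arma::uword n = 0; n < N; ++n) {
          const double v1 = x[idx4(n, 2 * h, 2 * w, c, N, H, W)];
          const double v2 = x[idx4(n, 2 * h + 1, 2 * w, c, N, H, W)];
          const double v3 = x[idx4(n, 2 * h, 2 * w + 1, c, N, H, W)];
          const double v4 = x[idx4(n, 2 * h + 1, 2 * w + 1, c, N, H, W)];
          double best = v1; int a = 1;
          if (v2 > best) { best = v2; a = 2; }
          if (v3 > best) { best = v3; a = 3; }
          if (v4 > best) { best = v4; a = 4; }
          const arma::uword o = idx4(n, h, w, c, N, Ho, Wo);
          out[o] = best;
          arg[o] = a;
        }
  return List::create(_["out"] = out, _["arg"] = arg);
}

// [[Rcpp::export]]
arma::vec cpp_maxpool_backward(const arma::vec& dout, IntegerVector arg,
                               IntegerVector in_dims) {
  const arma::uword N = in_dims[0], H = in_dims[1], W = in_dims[2],
                    C = in_dims[3];
  const arma::uword Ho = H / 2, Wo = W / 2;
  arma::vec dx(N * H * W * C, arma::fill::zeros);
  for (arma::uword c = 0; c < C; ++c)
    for (arma::uword w = 0; w < Wo; ++w)
      for (arma::uword h = 0; h < Ho; ++h)
        for (arma::uword n = 0; n < N; ++n) {
          const arma::uword o = idx4(n, h, w, c, N, Ho, Wo);
          const int a = arg[o];
          const arma::uword hh = 2 * h + (a == 2 || a == 4 ? 1 : 0);
          const arma::uword ww = 2 * w + (a == 3 || a == 4 ? 1 : 0);
          dx[idx4(n, hh, ww, c, N, H, W)] = dout[o];
        }
  return dx;
}

// Instance normalization fused with ReLU. Each (sample, channel) plane of
// the (N, H, W, C) activation is standardized over its H*W positions:
// y = (x - mean) / sqrt(var + eps), out = max(0, y). Deterministic, no
// learnable parameters or running statistics; cancels per-image
// multiplicative exposure within a channel.
// [[Rcpp::export]]
List cpp_in_relu_forward(const arma::vec& x, IntegerVector dims,
                         double eps) {
  const arma::uword N = dims[0], H = dims[1], W = dims[2], C = dims[3];
  const arma::uword M = H * W;
  arma::vec y(N * M * C), out(N * M * C), sd(N * C);
  for (arma::uword c = 0; c < C; ++c)
    for (arma::uword n = 0; n < N; ++n) {
      double sum = 0, sq = 0;
      for (arma::uword m = 0; m < M; ++m) {
        const double v = x[n + N * (m + M * c)];
        sum += v; sq += v * v;
      }
      const double mu = sum / M;
      const double var = sq / M - mu * mu;
      const double s = std::sqrt(var > 0 ? var + eps : eps);
      sd[n + N * c] = s;
      for (arma::uword m = 0; m < M; ++m) {
        const arma::uword i = n + N * (m + M * c);
        const double yy = (x[i] - mu) / s;
        y[i] = yy;
        out[i] = yy > 0 ? yy : 0.0;
      }
    }
  return List::create(_["out"] = out, _["y"] = y, _["sd"] = sd);
}

// [[Rcpp::export]]
arma::vec cpp_in_relu_backward(const arma::vec& dout, const arma::vec& y,
                               const arma::vec& sd, IntegerVector dims) {
  const arma::uword N = dims[0], H = dims[1], W = dims[2], C = dims[3];
  const arma::uword M = H * W;
  arma::vec dx(N * M * C);
  for (arma::uword c = 0; c < C; ++c)
    for (arma::uword n = 0; n < N; ++n) {
      double mh = 0, mhy = 0;
      for (arma::uword m = 0; m < M; ++m) {
        const arma::uword i = n + N * (m + M * c);
        const double h = y[i] > 0 ? dout[i] : 0.0;  // ReLU gate
        mh += h; mhy += h * y[i];
      }
      mh /= M; mhy /= M;
      const double s = sd[n + N * c];
      for (arma::uword m = 0; m < M; ++m) {
        const arma::uword i = n + N * (m + M * c);
        const double h = y[i] > 0 ? dout[i] : 0.0;
        dx[i] = (h - mh - y[i] * mhy) / s;
      }
    }
  return dx;
}

// Bilinear rotation of an (H, W, C) image about its center, zero fill.
// [[Rcpp::export]]
NumericVector cpp_rotate_bilinear(const NumericVector& img,
                                  IntegerVector dims, double angle_deg) {
  const int H = dims[0], W = dims[1], C = dims[2];
  const double th = angle_deg * M_PI / 180.0;
  const double ct = std::cos(th), st = std::sin(th);
  const double cy = (H + 1) / 2.0, cx = (W + 1) / 2.0;
  NumericVector out(H * W * C);
  for (int w = 0; w < W; ++w) {
    const double xg = (w + 1) - cx;
    for (int h = 0; h < H; ++h) {
      const double yg = (h + 1) - cy;
      const double sx = ct * xg + st * yg + cx;
      const double sy = -st * xg + ct * yg + cy;
      const int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy);
      const double fx = sx - x0, fy = sy - y0;
      for (int c = 0; c < C; ++c) {
        const double* p = &img[0] + (size_t)H * W * c;
        auto at = [&](int yy, int xx) -> double {
          if (yy < 1 || yy > H || xx < 1 || xx > W) return 0.0;
          return p[(yy - 1) + H * (xx - 1)];
        };
        out[h + H * (w + (size_t)W * c)] =
            at(y0, x0) * (1 - fx) * (1 - fy) + at(y0, x0 + 1) * fx * (1 - fy) +
            at(y0 + 1, x0) * (1 - fx) * fy + at(y0 + 1, x0 + 1) * fx * fy;
      }
    }
  }
  return out;
}
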