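// Low-level tensor kernels for the network engine.
//
// Tensor layout: 4-D R arrays with dims (H, W, C, N), column-major, so the
// linear index of (h, w, c, n) is h + H*(w + W*(c + C*n)) (0-based).
// Convolutions use im2col + GEMM via Armadillo; zero padding.
//
// Continuous image coordinates put the center of pixel (row r, col c)
// (1-based) at (x, y) = (c - 0.5, r - 0.5), matching the R-level bilinear
// crop; RoI boxes are 0-based half-open rectangles in those units.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// im2col for one sample: x is (H,W,C), result (Ho*Wo, k*k*C)
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, arma::mat& cols) {
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int col = i + kh * (j + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + j;
          bool wok = wi >= 0 && wi < W;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + i;
            double v = 0.0;
            if (wok && hi >= 0 && hi < H) {
              v = x[hi + H * (wi + W * c)];
            }
            cols(ho + Ho * wo, col) = v;
          }
        }
      }
    }
  }
}

// scatter-add of column gradients back to the input image
static void col2im(const arma::mat& cols, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, double* dx) {
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int col = i + kh * (j + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + j;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + i;
            if (hi < 0 || hi >= H) continue;
            dx[hi + H * (wi + W * c)] += cols(ho + Ho * wo, col);
          }
        }
      }
    }
  }
}

// Forward with retained im2col workspace; the backward pass then skips
// the im2col recomputation. The workspace is an (Ho*Wo, k*k*C, N) cube.
// [[Rcpp::export(name = ".conv2d_fwd_ws")]]
List conv2d_fwd_ws(NumericVector x, NumericVector w, NumericVector b,
                   int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: channel mismatch");
  int Ho = out_size(H, kh, stride, pad);
  int Wo = out_size(W, kw, stride, pad);
  if (Ho <= 0 || Wo <= 0) stop("conv2d: output size would be non-positive");
  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  int k2c = kh * kw * Cin;
  NumericVector cols_r((size_t)Ho * Wo * k2c * N);
  cols_r.attr("dim") = IntegerVector::create(Ho * Wo, k2c, N);
  arma::mat Wm(const_cast<double*>(w.begin()), k2c, Cout, false);
  for (int n = 0; n < N; ++n) {
    arma::mat cols(cols_r.begin() + (size_t)n * Ho * Wo * k2c,
                   Ho * Wo, k2c, false, true);
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, stride, pad,
           Ho, Wo, cols);
    arma::mat out = cols * Wm;
    double* yp = y.begin() + (size_t)n * Ho * Wo * Cout;
    for (int c = 0; c < Cout; ++c) {
      double bias = b.size() > 0 ? b[c] : 0.0;
      for (int p = 0; p < Ho * Wo; ++p)
        yp[p + (size_t)Ho * Wo * c] = out(p, c) + bias;
    }
  }
  return List::create(_["y"] = y, _["cols"] = cols_r);
}

// [[Rcpp::export(name = ".conv2d_bwd_ws")]]
List conv2d_bwd_ws(NumericVector cols, NumericVector w, NumericVector dy,
                   IntegerVector xdim, int stride, int pad, bool need_dx) {
  IntegerVector wd = w.attr("dim");
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  int Ho = out_size(H, kh, stride, pad);
  int Wo = out_size(W, kw, stride, pad);
  int k2c = kh * kw * Cin;
  NumericVector dw(k2c * Cout);
  dw.attr("dim") = wd;
  NumericVector db(Cout);
  NumericVector dx;
  if (need_dx) {
    dx = NumericVector((size_t)H * W * C * N);
    dx.attr("dim") = xdim;
  }
  arma::mat Wm(const_cast<double*>(w.begin()), k2c, Cout, false);
  arma::mat dWm(dw.begin(), k2c, Cout, false);
  for (int n = 0; n < N; ++n) {
    arma::mat sub(const_cast<double*>(cols.begin()) + (size_t)n * Ho * Wo * k2c,
                  Ho * Wo, k2c, false);
    arma::mat dYm(const_cast<double*>(dy.begin()) + (size_t)n * Ho * Wo * Cout,
                  Ho * Wo, Cout, false);
    dWm += sub.t() * dYm;
    for (int c = 0; c < Cout; ++c) db[c] += arma::accu(dYm.col(c));
    if (need_dx) {
      arma::mat dcols = dYm * Wm.t();
      col2im(dcols, H, W, C, kh, kw, stride, pad, Ho, Wo,
             dx.begin() + (size_t)n * H * W * C);
    }
  }
  return List::create(_["dx"] = need_dx ? (SEXP)dx : R_NilValue,
                      _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: channel mismatch");
  int Ho = out_size(H, kh, stride, pad);
  int Wo = out_size(W, kw, stride, pad);
  if (Ho <= 0 || Wo <= 0) stop("conv2d: output size would be non-positive");
  NumericVector y(Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * Cin, Cout, false);
  arma::mat cols(Ho * Wo, kh * kw * Cin);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, stride, pad,
           Ho, Wo, cols);
    arma::mat out = cols * Wm;  // (Ho*Wo, Cout)
    double* yp = y.begin() + (size_t)n * Ho * Wo * Cout;
    for (int c = 0; c < Cout; ++c) {
      double bias = b.size() > 0 ? b[c] : 0.0;
      for (int p = 0; p < Ho * Wo; ++p) yp[p + (size_t)Ho * Wo * c] = out(p, c) + bias;
    }
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                int stride, int pad, bool need_dx) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  int Ho = out_size(H, kh, stride, pad);
  int Wo = out_size(W, kw, stride, pad);
  NumericVector dw(kh * kw * Cin * Cout);
  dw.attr("dim") = wd;
  NumericVector db(Cout);
  NumericVector dx;
  if (need_dx) {
    dx = NumericVector(x.size());
    dx.attr("dim") = xd;
  }
  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * Cin, Cout, false);
  arma::mat dWm(dw.begin(), kh * kw * Cin, Cout, false);
  arma::mat cols(Ho * Wo, kh * kw * Cin);
  for (int n = 0; n < N; ++n) {
    arma::mat dYm(const_cast<double*>(dy.begin()) + (size_t)n * Ho * Wo * Cout,
                  Ho * Wo, Cout, false);
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, stride, pad,
           Ho, Wo, cols);
    dWm += cols.t() * dYm;
    for (int c = 0; c < Cout; ++c) db[c] += arma::accu(dYm.col(c));
    if (need_dx) {
      arma::mat dcols = dYm * Wm.t();
      col2im(dcols, H, W, C, kh, kw, stride, pad, Ho, Wo,
             dx.begin() + (size_t)n * H * W * C);
    }
  }
  return List::create(_["dx"] = need_dx ? (SEXP)dx : R_NilValue,
                      _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export(name = ".maxpool_fwd")]]
List maxpool_fwd(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = out_size(H, k, stride, pad);
  int Wo = out_size(W, k, stride, pad);
  NumericVector y(Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector arg(y.size());
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      size_t xoff = (size_t)H * W * (c + (size_t)C * n);
      size_t yoff = (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -INFINITY;
          int besti = -1;
          for (int j = 0; j < k; ++j) {
            int wi = wo * stride - pad + j;
            if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < k; ++i) {
              int hi = ho * stride - pad + i;
              if (hi < 0 || hi >= H) continue;
              double v = xp[xoff + hi + (size_t)H * wi];
              if (v > best) { best = v; besti = (int)(xoff + hi + (size_t)H * wi); }
            }
          }
          y[yoff + ho + (size_t)Ho * wo] = best;
          arg[yoff + ho + (size_t)Ho * wo] = besti;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["arg"] = arg);
}

// [[Rcpp::export(name = ".maxpool_bwd")]]
NumericVector maxpool_bwd(NumericVector dy, IntegerVector arg,
                          IntegerVector xdim) {
  size_t sz = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(sz);
  dx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < dy.size(); ++i) {
    if (arg[i] >= 0) dx[arg[i]] += dy[i];
  }
  return dx;
}

// bilinear interpolation helper: value of channel plane at continuous
// (x, y) with pixel centers at half-integers; edge-clamped.
static inline void bilin_coef(double coord, int limit,
                              int& i0, int& i1, double& w1) {
  double f = coord - 0.5;
  if (f < 0) f = 0;
  if (f > limit - 1) f = limit - 1;
  i0 = (int)std::floor(f);
  i1 = i0 + 1 < limit ? i0 + 1 : limit - 1;
  w1 = f - i0;
}

// [[Rcpp::export(name = ".roi_align_fwd")]]
NumericVector roi_align_fwd(NumericVector feat, NumericMatrix boxes,
                            int out_size_, int sampling) {
  IntegerVector fd = feat.attr("dim");
  int H = fd[0], W = fd[1], C = fd[2];
  int n = boxes.nrow();
  NumericVector y((size_t)out_size_ * out_size_ * C * n);
  y.attr("dim") = IntegerVector::create(out_size_, out_size_, C, n);
  const double* fp = feat.begin();
  int nb = out_size_ * out_size_;
  for (int b = 0; b < n; ++b) {
    double x0 = boxes(b, 0), y0 = boxes(b, 1), x1 = boxes(b, 2), y1 = boxes(b, 3);
    double bw = std::max(x1 - x0, 1e-6), bh = std::max(y1 - y0, 1e-6);
    double binw = bw / out_size_, binh = bh / out_size_;
    int g = sampling > 0 ? sampling : std::max(1, (int)std::ceil(binw));
    double denom = 1.0 / (g * g);
    int ns = g * g;
    // precompute the 4 corner offsets + weights for every sample point
    std::vector<int> o00(nb * ns), o01(nb * ns), o10(nb * ns), o11(nb * ns);
    std::vector<double> w00(nb * ns), w01(nb * ns), w10(nb * ns), w11(nb * ns);
    int t = 0;
    for (int pw = 0; pw < out_size_; ++pw) {
      for (int ph = 0; ph < out_size_; ++ph) {
        for (int iy = 0; iy < g; ++iy) {
          double sy = y0 + (ph + (iy + 0.5) / g) * binh;
          int r0, r1; double wy;
          bilin_coef(sy, H, r0, r1, wy);
          for (int ix = 0; ix < g; ++ix) {
            double sx = x0 + (pw + (ix + 0.5) / g) * binw;
            int c0, c1; double wx;
            bilin_coef(sx, W, c0, c1, wx);
            o00[t] = r0 + H * c0; o01[t] = r0 + H * c1;
            o10[t] = r1 + H * c0; o11[t] = r1 + H * c1;
            w00[t] = (1 - wy) * (1 - wx); w01[t] = (1 - wy) * wx;
            w10[t] = wy * (1 - wx); w11[t] = wy * wx;
            ++t;
          }
        }
      }
    }
    for (int c = 0; c < C; ++c) {
      const double* plane = fp + (size_t)H * W * c;
      double* out = y.begin() + (size_t)nb * (c + (size_t)C * b);
      t = 0;
      for (int p = 0; p < nb; ++p) {
        double acc = 0.0;
        for (int ss = 0; ss < ns; ++ss, ++t) {
          acc += w00[t] * plane[o00[t]] + w01[t] * plane[o01[t]]
               + w10[t] * plane[o10[t]] + w11[t] * plane[o11[t]];
        }
        // bins are stored row-fastest: p = ph + out_size_ * pw
        out[p] = acc * denom;
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".roi_align_bwd")]]
NumericVector roi_align_bwd(NumericVector dy, NumericMatrix boxes,
                            IntegerVector fdim, int out_size_, int sampling) {
  int H = fdim[0], W = fdim[1], C = fdim[2];
  int n = boxes.nrow();
  NumericVector dfeat((size_t)H * W * C);
  dfeat.attr("dim") = IntegerVector::create(H, W, C);
  int nb = out_size_ * out_size_;
  for (int b = 0; b < n; ++b) {
    double x0 = boxes(b, 0), y0 = boxes(b, 1), x1 = boxes(b, 2), y1 = boxes(b, 3);
    double bw = std::max(x1 - x0, 1e-6), bh = std::max(y1 - y0, 1e-6);
    double binw = bw / out_size_, binh = bh / out_size_;
    int g = sampling > 0 ? sampling : std::max(1, (int)std::ceil(binw));
    double denom = 1.0 / (g * g);
    int ns = g * g;
    std::vector<int> o00(nb * ns), o01(nb * ns), o10(nb * ns), o11(nb * ns);
    std::vector<double> w00(nb * ns), w01(nb * ns), w10(nb * ns), w11(nb * ns);
    int t = 0;
    for (int pw = 0; pw < out_size_; ++pw) {
      for (int ph = 0; ph < out_size_; ++ph) {
        for (int iy = 0; iy < g; ++iy) {
          double sy = y0 + (ph + (iy + 0.5) / g) * binh;
          int r0, r1; double wy;
          bilin_coef(sy, H, r0, r1, wy);
          for (int ix = 0; ix < g; ++ix) {
            double sx = x0 + (pw + (ix + 0.5) / g) * binw;
            int c0, c1; double wx;
            bilin_coef(sx, W, c0, c1, wx);
            o00[t] = r0 + H * c0; o01[t] = r0 + H * c1;
            o10[t] = r1 + H * c0; o11[t] = r1 + H * c1;
            w00[t] = (1 - wy) * (1 - wx); w01[t] = (1 - wy) * wx;
            w10[t] = wy * (1 - wx); w11[t] = wy * wx;
            ++t;
          }
        }
      }
    }
    for (int c = 0; c < C; ++c) {
      double* plane = dfeat.begin() + (size_t)H * W * c;
      const double* gin = dy.begin() + (size_t)nb * (c + (size_t)C * b);
      t = 0;
      for (int p = 0; p < nb; ++p) {
        double go = gin[p] * denom;
        if (go == 0) { t += ns; continue; }
        for (int ss = 0; ss < ns; ++ss, ++t) {
          plane[o00[t]] += go * w00[t];
          plane[o01[t]] += go * w01[t];
          plane[o10[t]] += go * w10[t];
          plane[o11[t]] += go * w11[t];
        }
      }
    }
  }
  return dfeat;
}
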