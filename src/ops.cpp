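// Low-level tensor kernels for the Wave-Net segmentation stack.
//
// All 4-D tensors are R arrays with dim (H, W, C, N), column-major, so the
// (h, w) plane of one channel of one sample is a contiguous H*W block.
// Gradients mirror the forward layouts exactly.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ---------------------------------------------------------------------------
// depthwise 3x3 convolution, zero padding 1, stride 1
// w: (3, 3, C) taps, b: (C)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_dwconv3_fwd(const NumericVector& x, const NumericVector& w,
                              const NumericVector& b,
                              int H, int W, int C, int N) {
  NumericVector y = Rcpp::no_init(static_cast<R_xlen_t>(H) * W * C * N);
  const double* xp0 = x.begin();
  double* yp0 = y.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* wp = &w[9 * c];
      const double bias = b[c];
      const double* xp = xp0 + static_cast<R_xlen_t>(H) * W * (c + static_cast<R_xlen_t>(C) * n);
      double* yp = yp0 + static_cast<R_xlen_t>(H) * W * (c + static_cast<R_xlen_t>(C) * n);
      for (int wj = 0; wj < W; ++wj) {
        const bool winner = (wj > 0 && wj < W - 1);
        if (winner) {
          // interior columns: only the row borders need checks
          const double* cm = xp + static_cast<R_xlen_t>(H) * (wj - 1);
          const double* cc = xp + static_cast<R_xlen_t>(H) * wj;
          const double* cp = xp + static_cast<R_xlen_t>(H) * (wj + 1);
          double* out = yp + static_cast<R_xlen_t>(H) * wj;
          for (int hi = 1; hi < H - 1; ++hi) {
            out[hi] = bias +
              cm[hi - 1] * wp[0] + cm[hi] * wp[1] + cm[hi + 1] * wp[2] +
              cc[hi - 1] * wp[3] + cc[hi] * wp[4] + cc[hi + 1] * wp[5] +
              cp[hi - 1] * wp[6] + cp[hi] * wp[7] + cp[hi + 1] * wp[8];
          }
        }
        for (int hi = 0; hi < H; ++hi) {
          if (winner && hi > 0 && hi < H - 1) { hi = H - 2; continue; }
          double acc = bias;
          for (int dj = -1; dj <= 1; ++dj) {
            const int wq = wj + dj;
            if (wq < 0 || wq >= W) continue;
            const double* col = xp + static_cast<R_xlen_t>(H) * wq;
            const double* wcol = wp + 3 * (dj + 1);
            for (int di = -1; di <= 1; ++di) {
              const int hq = hi + di;
              if (hq < 0 || hq >= H) continue;
              acc += col[hq] * wcol[di + 1];
            }
          }
          yp[hi + static_cast<R_xlen_t>(H) * wj] = acc;
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(H, W, C, N);
  return y;
}

// [[Rcpp::export]]
List cpp_dwconv3_bwd(const NumericVector& x, const NumericVector& w,
                     const NumericVector& gy,
                     int H, int W, int C, int N) {
  NumericVector gx = Rcpp::no_init(static_cast<R_xlen_t>(H) * W * C * N);
  NumericVector gw(9 * C);
  NumericVector gb(C);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* wp = &w[9 * c];
      double* gwp = &gw[9 * c];
      const R_xlen_t slab = static_cast<R_xlen_t>(H) * W * (c + static_cast<R_xlen_t>(C) * n);
      const double* xp = x.begin() + slab;
      const double* gp = gy.begin() + slab;
      double* gxp = gx.begin() + slab;
      // gb: plain sum of the output gradient
      double gbc = 0.0;
      for (R_xlen_t k = 0; k < static_cast<R_xlen_t>(H) * W; ++k) gbc += gp[k];
      gb[c] += gbc;
      // gx: correlation of gy with the flipped kernel (same zero padding)
      for (int wj = 0; wj < W; ++wj) {
        const bool winner = (wj > 0 && wj < W - 1);
        if (winner) {
          const double* cm = gp + static_cast<R_xlen_t>(H) * (wj - 1);
          const double* cc = gp + static_cast<R_xlen_t>(H) * wj;
          const double* cp = gp + static_cast<R_xlen_t>(H) * (wj + 1);
          double* out = gxp + static_cast<R_xlen_t>(H) * wj;
          for (int hi = 1; hi < H - 1; ++hi) {
            out[hi] =
              cm[hi - 1] * wp[8] + cm[hi] * wp[7] + cm[hi + 1] * wp[6] +
              cc[hi - 1] * wp[5] + cc[hi] * wp[4] + cc[hi + 1] * wp[3] +
              cp[hi - 1] * wp[2] + cp[hi] * wp[1] + cp[hi + 1] * wp[0];
          }
        }
        for (int hi = 0; hi < H; ++hi) {
          if (winner && hi > 0 && hi < H - 1) { hi = H - 2; continue; }
          double acc = 0.0;
          for (int dj = -1; dj <= 1; ++dj) {
            const int wq = wj + dj;
            if (wq < 0 || wq >= W) continue;
            for (int di = -1; di <= 1; ++di) {
              const int hq = hi + di;
              if (hq < 0 || hq >= H) continue;
              acc += gp[hq + static_cast<R_xlen_t>(H) * wq] * wp[8 - ((di + 1) + 3 * (dj + 1))];
            }
          }
          gxp[hi + static_cast<R_xlen_t>(H) * wj] = acc;
        }
      }
      // gw: one shifted dot product per tap
      for (int dj = -1; dj <= 1; ++dj) {
        for (int di = -1; di <= 1; ++di) {
          const int k = (di + 1) + 3 * (dj + 1);
          double acc = 0.0;
          const int w0 = std::max(0, -dj), w1 = std::min(W, W - dj);
          const int h0 = std::max(0, -di), h1 = std::min(H, H - di);
          for (int wj = w0; wj < w1; ++wj) {
            const double* gcol = gp + static_cast<R_xlen_t>(H) * wj;
            const double* xcol = xp + static_cast<R_xlen_t>(H) * (wj + dj);
            for (int hi = h0; hi < h1; ++hi)
              acc += gcol[hi] * xcol[hi + di];
          }
          gwp[k] += acc;
        }
      }
    }
  }
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  gw.attr("dim") = IntegerVector::create(3, 3, C);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// ---------------------------------------------------------------------------
// pointwise 1x1 convolution (channel mixing): per-sample GEMM
// w: (Cin, Cout), b: (Cout)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_conv1x1_fwd(const NumericVector& x, const NumericMatrix& w,
                              const NumericVector& b,
                              int H, int W, int Cin, int N) {
  const int Cout = w.ncol();
  const R_xlen_t P = static_cast<R_xlen_t>(H) * W;
  NumericVector y = Rcpp::no_init(P * Cout * N);
  arma::mat Wm(const_cast<double*>(w.begin()), Cin, Cout, false, true);
  arma::rowvec bb(const_cast<double*>(b.begin()), Cout, false, true);
  for (int n = 0; n < N; ++n) {
    arma::mat X(const_cast<double*>(x.begin()) + P * Cin * n, P, Cin, false, true);
    arma::mat Y(y.begin() + P * Cout * n, P, Cout, false, true);
    Y = X * Wm;
    Y.each_row() += bb;
  }
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  return y;
}

// [[Rcpp::export]]
List cpp_conv1x1_bwd(const NumericVector& x, const NumericMatrix& w,
                     const NumericVector& gy,
                     int H, int W, int Cin, int N) {
  const int Cout = w.ncol();
  const R_xlen_t P = static_cast<R_xlen_t>(H) * W;
  NumericVector gx = Rcpp::no_init(P * Cin * N);
  NumericMatrix gw(Cin, Cout);
  NumericVector gb(Cout);
  arma::mat Wm(const_cast<double*>(w.begin()), Cin, Cout, false, true);
  arma::mat GW(gw.begin(), Cin, Cout, false, true);
  arma::rowvec GB(gb.begin(), Cout, false, true);
  for (int n = 0; n < N; ++n) {
    arma::mat X(const_cast<double*>(x.begin()) + P * Cin * n, P, Cin, false, true);
    arma::mat GY(const_cast<double*>(gy.begin()) + P * Cout * n, P, Cout, false, true);
    arma::mat GX(gx.begin() + P * Cin * n, P, Cin, false, true);
    GX = GY * Wm.t();
    GW += X.t() * GY;
    GB += arma::sum(GY, 0);
  }
  gx.attr("dim") = IntegerVector::create(H, W, Cin, N);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// ---------------------------------------------------------------------------
// 2x2 max pooling, stride 2 (H, W even)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_maxpool2_fwd(const NumericVector& x, int H, int W, int C, int N) {
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y = Rcpp::no_init(static_cast<R_xlen_t>(Ho) * Wo * C * N);
  IntegerVector idx(static_cast<R_xlen_t>(Ho) * Wo * C * N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + static_cast<R_xlen_t>(H) * W * (c + static_cast<R_xlen_t>(C) * n);
      const R_xlen_t oslab = static_cast<R_xlen_t>(Ho) * Wo * (c + static_cast<R_xlen_t>(C) * n);
      double* yp = y.begin() + oslab;
      int* ip = idx.begin() + oslab;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          const int h0 = 2 * ho, w0 = 2 * wo;
          int best = h0 + H * w0;
          double bv = xp[best];
          const int cand[3] = {h0 + 1 + H * w0, h0 + H * (w0 + 1), h0 + 1 + H * (w0 + 1)};
          for (int k = 0; k < 3; ++k) {
            if (xp[cand[k]] > bv) { bv = xp[cand[k]]; best = cand[k]; }
          }
          yp[ho + static_cast<R_xlen_t>(Ho) * wo] = bv;
          ip[ho + static_cast<R_xlen_t>(Ho) * wo] = best;
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(const IntegerVector& idx, const NumericVector& gy,
                               int H, int W, int C, int N) {
  const int Ho = H / 2, Wo = W / 2;
  NumericVector gx(static_cast<R_xlen_t>(H) * W * C * N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const R_xlen_t oslab = static_cast<R_xlen_t>(Ho) * Wo * (c + static_cast<R_xlen_t>(C) * n);
      const R_xlen_t islab = static_cast<R_xlen_t>(H) * W * (c + static_cast<R_xlen_t>(C) * n);
      const double* gp = gy.begin() + oslab;
      const int* ip = idx.begin() + oslab;
      double* gxp = gx.begin() + islab;
      const R_xlen_t n_out = static_cast<R_xlen_t>(Ho) * Wo;
      for (R_xlen_t k = 0; k < n_out; ++k) gxp[ip[k]] += gp[k];
    }
  }
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  return gx;
}

// ---------------------------------------------------------------------------
// bilinear 2x upsampling, half-pixel centers (align_corners = false), border
// clamped; backward is the exact transpose scatter
// ---------------------------------------------------------------------------

static void bilin2_coeffs(int Hin, int Hout, std::vector<int>& i0,
                          std::vector<int>& i1, std::vector<double>& t) {
  i0.resize(Hout); i1.resize(Hout); t.resize(Hout);
  for (int o = 0; o < Hout; ++o) {
    double src = (o + 0.5) / 2.0 - 0.5;
    int lo = static_cast<int>(std::floor(src));
    double tt = src - lo;
    int hi = lo + 1;
    if (lo < 0) lo = 0;
    if (hi > Hin - 1) hi = Hin - 1;
    if (lo > Hin - 1) lo = Hin - 1;
    i0[o] = lo; i1[o] = hi; t[o] = tt;
  }
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_fwd(const NumericVector& x, int H, int W, int C, int N) {
  // separable: rows then columns, sequential memory access
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y = Rcpp::no_init(static_cast<R_xlen_t>(Ho) * Wo * C * N);
  std::vector<int> r0, r1, c0, c1;
  std::vector<double> rt, ct;
  bilin2_coeffs(H, Ho, r0, r1, rt);
  bilin2_coeffs(W, Wo, c0, c1, ct);
  std::vector<double> tmp(static_cast<size_t>(Ho) * W);  // rows upsampled
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + static_cast<R_xlen_t>(H) * W * (c + static_cast<R_xlen_t>(C) * n);
      double* yp = y.begin() + static_cast<R_xlen_t>(Ho) * Wo * (c + static_cast<R_xlen_t>(C) * n);
      for (int w = 0; w < W; ++w) {
        const double* col = xp + static_cast<R_xlen_t>(H) * w;
        double* t = &tmp[static_cast<size_t>(Ho) * w];
        for (int ho = 0; ho < Ho; ++ho)
          t[ho] = (1 - rt[ho]) * col[r0[ho]] + rt[ho] * col[r1[ho]];
      }
      for (int wo = 0; wo < Wo; ++wo) {
        const double b = ct[wo];
        const double* tl = &tmp[static_cast<size_t>(Ho) * c0[wo]];
        const double* tr = &tmp[static_cast<size_t>(Ho) * c1[wo]];
        double* out = yp + static_cast<R_xlen_t>(Ho) * wo;
        for (int ho = 0; ho < Ho; ++ho)
          out[ho] = (1 - b) * tl[ho] + b * tr[ho];
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_bwd(const NumericVector& gy, int H, int W, int C, int N) {
  // H, W are the *input* (small) dims of the forward pass; adjoint of the
  // separable interpolation: columns first, then rows
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector gx(static_cast<R_xlen_t>(H) * W * C * N);
  std::vector<int> r0, r1, c0, c1;
  std::vector<double> rt, ct;
  bilin2_coeffs(H, Ho, r0, r1, rt);
  bilin2_coeffs(W, Wo, c0, c1, ct);
  std::vector<double> tmp(static_cast<size_t>(Ho) * W);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* gp = gy.begin() + static_cast<R_xlen_t>(Ho) * Wo * (c + static_cast<R_xlen_t>(C) * n);
      double* gxp = gx.begin() + static_cast<R_xlen_t>(H) * W * (c + static_cast<R_xlen_t>(C) * n);
      std::fill(tmp.begin(), tmp.end(), 0.0);
      for (int wo = 0; wo < Wo; ++wo) {
        const double b = ct[wo];
        const double* g = gp + static_cast<R_xlen_t>(Ho) * wo;
        double* tl = &tmp[static_cast<size_t>(Ho) * c0[wo]];
        double* tr = &tmp[static_cast<size_t>(Ho) * c1[wo]];
        for (int ho = 0; ho < Ho; ++ho) {
          tl[ho] += (1 - b) * g[ho];
          tr[ho] += b * g[ho];
        }
      }
      for (int w = 0; w < W; ++w) {
        const double* t = &tmp[static_cast<size_t>(Ho) * w];
        double* col = gxp + static_cast<R_xlen_t>(H) * w;
        for (int ho = 0; ho < Ho; ++ho) {
          col[r0[ho]] += (1 - rt[ho]) * t[ho];
          col[r1[ho]] += rt[ho] * t[ho];
        }
      }
    }
  }
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  return gx;
}

// ---------------------------------------------------------------------------
// batch normalization over (H, W, N) per channel
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_bn_fwd(const NumericVector& x, const NumericVector& gamma,
                const NumericVector& beta, double eps,
                int H, int W, int C, int N) {
  const R_xlen_t P = static_cast<R_xlen_t>(H) * W;
  const double M = static_cast<double>(P) * N;
  NumericVector y = Rcpp::no_init(P * C * N);
  NumericVector mean(C), var(C), invstd(C);
  for (int c = 0; c < C; ++c) {
    double s = 0.0, s2 = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* xp = x.begin() + P * (c + static_cast<R_xlen_t>(C) * n);
      for (R_xlen_t k = 0; k < P; ++k) { s += xp[k]; s2 += xp[k] * xp[k]; }
    }
    const double mu = s / M;
    double v = s2 / M - mu * mu;
    if (v < 0) v = 0;
    const double is = 1.0 / std::sqrt(v + eps);
    mean[c] = mu; var[c] = v; invstd[c] = is;
    const double g = gamma[c], bb = beta[c];
    const double a = g * is, bshift = bb - g * is * mu;
    for (int n = 0; n < N; ++n) {
      const R_xlen_t slab = P * (c + static_cast<R_xlen_t>(C) * n);
      const double* xp = x.begin() + slab;
      double* yp = y.begin() + slab;
      for (R_xlen_t k = 0; k < P; ++k)
        yp[k] = a * xp[k] + bshift;
    }
  }
  y.attr("dim") = IntegerVector::create(H, W, C, N);
  return List::create(_["y"] = y, _["mean"] = mean,
                      _["var"] = var, _["invstd"] = invstd);
}

// [[Rcpp::export]]
List cpp_bn_bwd(const NumericVector& gy, const NumericVector& x,
                const NumericVector& mean, const NumericVector& invstd,
                const NumericVector& gamma,
                int H, int W, int C, int N) {
  const R_xlen_t P = static_cast<R_xlen_t>(H) * W;
  const double M = static_cast<double>(P) * N;
  NumericVector gx = Rcpp::no_init(P * C * N);
  NumericVector ggamma(C), gbeta(C);
  for (int c = 0; c < C; ++c) {
    const double mu = mean[c], is = invstd[c];
    double s1 = 0.0, s2 = 0.0;
    for (int n = 0; n < N; ++n) {
      const R_xlen_t slab = P * (c + static_cast<R_xlen_t>(C) * n);
      const double* gp = gy.begin() + slab;
      const double* xp = x.begin() + slab;
      for (R_xlen_t k = 0; k < P; ++k) { s1 += gp[k]; s2 += gp[k] * (xp[k] - mu) * is; }
    }
    ggamma[c] = s2; gbeta[c] = s1;
    const double gis = gamma[c] * is;
    const double m1 = s1 / M, m2 = s2 / M;
    for (int n = 0; n < N; ++n) {
      const R_xlen_t slab = P * (c + static_cast<R_xlen_t>(C) * n);
      const double* gp = gy.begin() + slab;
      const double* xp = x.begin() + slab;
      double* gxp = gx.begin() + slab;
      for (R_xlen_t k = 0; k < P; ++k)
        gxp[k] = gis * (gp[k] - m1 - (xp[k] - mu) * is * m2);
    }
  }
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma, _["gbeta"] = gbeta);
}

// ---------------------------------------------------------------------------
// local boxcar statistics with symmetric-reflect padding (helper for the Lee
// family of filters and for coefficient-of-variation estimation)
// ---------------------------------------------------------------------------

static inline int reflect(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// [[Rcpp::export]]
List cpp_local_stats(const NumericMatrix& img, int win) {
  const int H = img.nrow(), W = img.ncol(), half = win / 2;
  NumericMatrix mu(H, W), va(H, W);
  const double M = static_cast<double>(win) * win;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double s = 0.0, s2 = 0.0;
      for (int dj = -half; dj <= half; ++dj) {
        const int jj = reflect(j + dj, W);
        for (int di = -half; di <= half; ++di) {
          const double v = img(reflect(i + di, H), jj);
          s += v; s2 += v * v;
        }
      }
      const double m = s / M;
      mu(i, j) = m;
      double v = s2 / M - m * m;
      va(i, j) = v > 0 ? v : 0.0;
    }
  }
  return List::create(_["mean"] = mu, _["var"] = va);
}

// ---------------------------------------------------------------------------
// Refined Lee despeckling filter
//
// Per pixel: a 3x3 template of sub-block means over the window estimates the
// local gradient direction; one of 8 edge-aligned half-windows (including the
// center line) is selected on the side whose mean is closest to the center
// block mean; MMSE weighting x = m + k (y - m) with
// k = clamp((var - m^2 Cu^2) / ((1 + Cu^2) var), 0, 1) is applied using the
// half-window statistics. k in [0,1] keeps the output inside the local range.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_refined_lee(const NumericMatrix& img, int win, double cu2) {
  const int H = img.nrow(), W = img.ncol(), half = win / 2;
  NumericMatrix out(H, W);
  const int off = half > 1 ? half - 1 : 1;   // sub-block center offset (2 for win=7)

  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      // 3x3 grid of 3x3 sub-block means, centers at offsets {-off, 0, off}
      double m[3][3];
      for (int a = 0; a < 3; ++a) {
        for (int b = 0; b < 3; ++b) {
          const int ci = i + (a - 1) * off, cj = j + (b - 1) * off;
          double s = 0.0;
          for (int di = -1; di <= 1; ++di)
            for (int dj = -1; dj <= 1; ++dj)
              s += img(reflect(ci + di, H), reflect(cj + dj, W));
          m[a][b] = s / 9.0;
        }
      }
      // gradient magnitudes across the template; 0 = horizontal-edge (vertical
      // gradient), 1 = vertical-edge, 2 = main diagonal, 3 = anti-diagonal
      const double g0 = std::fabs(m[0][1] - m[2][1]);
      const double g1 = std::fabs(m[1][0] - m[1][2]);
      const double g2 = std::fabs(m[0][0] - m[2][2]);
      const double g3 = std::fabs(m[0][2] - m[2][0]);
      int dir = 0; double gmax = g0;
      if (g1 > gmax) { dir = 1; gmax = g1; }
      if (g2 > gmax) { dir = 2; gmax = g2; }
      if (g3 > gmax) { dir = 3; gmax = g3; }
      // pick the side whose sub-block mean is closer to the center mean
      double mA, mB;  // the two opposing side means for the chosen direction
      switch (dir) {
        case 0: mA = m[0][1]; mB = m[2][1]; break;
        case 1: mA = m[1][0]; mB = m[1][2]; break;
        case 2: mA = m[0][0]; mB = m[2][2]; break;
        default: mA = m[0][2]; mB = m[2][0]; break;
      }
      const bool sideA = std::fabs(mA - m[1][1]) <= std::fabs(mB - m[1][1]);

      // half-window statistics (center line included)
      double s = 0.0, s2 = 0.0;
      int cnt = 0;
      for (int dj = -half; dj <= half; ++dj) {
        for (int di = -half; di <= half; ++di) {
          bool in;
          switch (dir) {
            case 0: in = sideA ? (di <= 0) : (di >= 0); break;          // rows
            case 1: in = sideA ? (dj <= 0) : (dj >= 0); break;          // cols
            case 2: in = sideA ? (di + dj <= 0) : (di + dj >= 0); break;
            default: in = sideA ? (dj - di >= 0) : (dj - di <= 0); break;
          }
          if (!in) continue;
          const double v = img(reflect(i + di, H), reflect(j + dj, W));
          s += v; s2 += v * v; ++cnt;
        }
      }
      const double mu = s / cnt;
      double va = s2 / cnt - mu * mu;
      if (va < 0) va = 0;
      double k = 0.0;
      if (va > 0) {
        k = (va - mu * mu * cu2) / ((1.0 + cu2) * va);
        if (k < 0) k = 0;
        if (k > 1) k = 1;
      }
      out(i, j) = mu + k * (img(i, j) - mu);
    }
  }
  return out;
}
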