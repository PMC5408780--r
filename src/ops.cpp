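#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Direct 3x3 stride-1 same-padding convolution kernels, fused batch-norm /
// ReLU kernels, and 2x2/stride-2 ceil-mode max pooling.  Convolutional
// activations are column-major R arrays with dims (H, W, N, C): row (y)
// fastest, then column (x), then sample, then channel, so each channel is
// one contiguous (H*W*N) plane and inner loops run down image columns.
//
// Weight matrices have dim (9 * C_in) x C_out with rows ordered
// (dy, dx, c_in), dy fastest.  The transposed-convolution needed for the
// input gradient is realized by calling the forward kernel with spatially
// flipped, channel-transposed weights (built on the R side).

// [[Rcpp::export]]
NumericVector cpp_conv3_fwd(NumericVector x, int H, int W, int N, int Cin,
                            NumericMatrix Wm, NumericVector b) {
  const int Cout = Wm.ncol();
  const int nrowW = Wm.nrow();
  const R_xlen_t plane = (R_xlen_t)H * W * N;
  NumericVector y(plane * Cout);
  const double *xp = x.begin();
  double *yp = y.begin();
  // weights transposed to (Cout) rows contiguous per patch-row index
  std::vector<double> wt((size_t)nrowW * Cout);
  for (int r = 0; r < nrowW; ++r)
    for (int co = 0; co < Cout; ++co)
      wt[(size_t)r * Cout + co] = Wm(r, co);
  std::vector<double> acc((size_t)H * Cout);
  for (int n = 0; n < N; ++n) {
    for (int xx = 0; xx < W; ++xx) {
      for (int yy = 0; yy < H; ++yy) {
        double *a = &acc[(size_t)yy * Cout];
        for (int co = 0; co < Cout; ++co) a[co] = b[co];
      }
      for (int ci = 0; ci < Cin; ++ci) {
        const double *xplane = xp + (R_xlen_t)ci * plane +
          ((R_xlen_t)n * W) * H;
        for (int dxk = -1; dxk <= 1; ++dxk) {
          const int sx = xx + dxk;
          if (sx < 0 || sx >= W) continue;
          const double *xcol = xplane + (R_xlen_t)sx * H;
          for (int dyk = -1; dyk <= 1; ++dyk) {
            const int r = (dyk + 1) + 3 * (dxk + 1) + 9 * ci;
            const double *wr = &wt[(size_t)r * Cout];
            const int y0 = dyk < 0 ? -dyk : 0;
            const int y1 = dyk > 0 ? H - dyk : H;
            for (int yy = y0; yy < y1; ++yy) {
              const double xv = xcol[yy + dyk];
              double *a = &acc[(size_t)yy * Cout];
              for (int co = 0; co < Cout; ++co) a[co] += wr[co] * xv;
            }
          }
        }
      }
      double *ycol = yp + ((R_xlen_t)n * W + xx) * H;
      for (int co = 0; co < Cout; ++co) {
        double *yc = ycol + (R_xlen_t)co * plane;
        for (int yy = 0; yy < H; ++yy) yc[yy] = acc[(size_t)yy * Cout + co];
      }
    }
  }
  return y;
}

// Weight and bias gradients only (the input gradient is a transposed
// convolution done via cpp_conv3_fwd with flipped weights).
// [[Rcpp::export]]
List cpp_conv3_dw(NumericVector x, int H, int W, int N, int Cin,
                  NumericVector dy, int Cout) {
  const R_xlen_t plane = (R_xlen_t)H * W * N;
  NumericMatrix dW(9 * Cin, Cout);
  NumericVector db(Cout);
  const double *xp = x.begin(), *dyp = dy.begin();
  for (int co = 0; co < Cout; ++co) {
    const double *gc = dyp + (R_xlen_t)co * plane;
    double s = 0.0;
    for (R_xlen_t i = 0; i < plane; ++i) s += gc[i];
    db[co] = s;
    for (int ci = 0; ci < Cin; ++ci) {
      const double *xc = xp + (R_xlen_t)ci * plane;
      for (int dxk = -1; dxk <= 1; ++dxk) {
        const int x0 = dxk < 0 ? -dxk : 0;
        const int x1 = dxk > 0 ? W - dxk : W;
        for (int dyk = -1; dyk <= 1; ++dyk) {
          const int y0 = dyk < 0 ? -dyk : 0;
          const int y1 = dyk > 0 ? H - dyk : H;
          double acc = 0.0;
          for (int n = 0; n < N; ++n) {
            for (int xx = x0; xx < x1; ++xx) {
              const double *gcol = gc + ((R_xlen_t)n * W + xx) * H;
              const double *xcol = xc + ((R_xlen_t)n * W + xx + dxk) * H + dyk;
              double a = 0.0;
              for (int yy = y0; yy < y1; ++yy) a += xcol[yy] * gcol[yy];
              acc += a;
            }
          }
          dW((dyk + 1) + 3 * (dxk + 1) + 9 * ci, co) = acc;
        }
      }
    }
  }
  return List::create(_["dW"] = dW, _["db"] = db);
}

// per-channel mean and mean of squares in one pass; a has C contiguous
// planes of m values
// [[Rcpp::export]]
List cpp_channel_stats(NumericVector a, double m_, int C) {
  const R_xlen_t m = (R_xlen_t)m_;
  NumericVector mu(C), ex2(C);
  const double *ap = a.begin();
  for (int c = 0; c < C; ++c) {
    const double *p = ap + (R_xlen_t)c * m;
    double s = 0.0, s2 = 0.0;
    for (R_xlen_t i = 0; i < m; ++i) { s += p[i]; s2 += p[i] * p[i]; }
    mu[c] = s / m; ex2[c] = s2 / m;
  }
  return List::create(_["mu"] = mu, _["ex2"] = ex2);
}

// fused normalize + scale/shift + optional ReLU; returns y and (optionally)
// the normalized xhat needed for the backward pass
// [[Rcpp::export]]
List cpp_bnrelu_fwd(NumericVector a, double m_, int C, NumericVector gamma,
                    NumericVector beta, NumericVector mu, NumericVector ivar,
                    bool relu, bool want_xhat) {
  const R_xlen_t m = (R_xlen_t)m_;
  NumericVector y(a.size());
  NumericVector xhat(want_xhat ? a.size() : 0);
  const double *ap = a.begin();
  double *yp = y.begin();
  double *xp = want_xhat ? xhat.begin() : (double *)nullptr;
  for (int c = 0; c < C; ++c) {
    const double muc = mu[c], iv = ivar[c], g = gamma[c], bt = beta[c];
    const double *pa = ap + (R_xlen_t)c * m;
    double *py = yp + (R_xlen_t)c * m;
    double *px = want_xhat ? xp + (R_xlen_t)c * m : (double *)nullptr;
    for (R_xlen_t i = 0; i < m; ++i) {
      const double xh = (pa[i] - muc) * iv;
      if (want_xhat) px[i] = xh;
      const double v = g * xh + bt;
      py[i] = (relu && v < 0) ? 0.0 : v;
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat);
}

// fused backward through ReLU + batch norm.  dout is the gradient at the
// post-ReLU output, y the post-ReLU output itself (for the mask), xhat the
// cached normalized input.  In train mode applies the full batch-norm
// backward; in eval mode the affine chain rule only.
// [[Rcpp::export]]
List cpp_bnrelu_bwd(NumericVector dout, NumericVector y, NumericVector xhat,
                    double m_, int C, NumericVector gamma, NumericVector ivar,
                    bool relu, bool train) {
  const R_xlen_t m = (R_xlen_t)m_;
  NumericVector dx(dout.size());
  NumericVector dgamma(C), dbeta(C);
  const double *dp = dout.begin(), *yp = y.begin(), *xp = xhat.begin();
  double *op = dx.begin();
  for (int c = 0; c < C; ++c) {
    const double g = gamma[c], iv = ivar[c];
    const double *pd = dp + (R_xlen_t)c * m;
    const double *py = yp + (R_xlen_t)c * m;
    const double *px = xp + (R_xlen_t)c * m;
    double *po = op + (R_xlen_t)c * m;
    double s1 = 0.0, s2 = 0.0;
    for (R_xlen_t i = 0; i < m; ++i) {
      const double dm = (relu && py[i] <= 0) ? 0.0 : pd[i];
      s1 += dm; s2 += dm * px[i];
    }
    dbeta[c] = s1; dgamma[c] = s2;
    if (train) {
      const double a1 = g * s1 / m, a2 = g * s2 / m;
      for (R_xlen_t i = 0; i < m; ++i) {
        const double dm = (relu && py[i] <= 0) ? 0.0 : pd[i];
        po[i] = iv * (dm * g - a1 - px[i] * a2);
      }
    } else {
      const double giv = g * iv;
      for (R_xlen_t i = 0; i < m; ++i) {
        const double dm = (relu && py[i] <= 0) ? 0.0 : pd[i];
        po[i] = dm * giv;
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// 2x2 max pooling with stride 2 and ceil-mode output size over S
// independent (H, W) slices.  Returns pooled values and 0-based flat
// argmax indices.
// [[Rcpp::export]]
List cpp_maxpool(NumericVector x, int H, int W, int S) {
  const int Ho = (H + 1) / 2, Wo = (W + 1) / 2;
  const R_xlen_t osz = (R_xlen_t)Ho * Wo * S;
  NumericVector out(osz);
  NumericVector arg(osz);        // double holds indices exactly to 2^53
  const double *xp = x.begin();
  double *op = out.begin(), *ap = arg.begin();
  R_xlen_t o = 0;
  for (int s = 0; s < S; ++s) {
    const R_xlen_t base = (R_xlen_t)s * H * W;
    for (int ox = 0; ox < Wo; ++ox) {
      for (int oy = 0; oy < Ho; ++oy, ++o) {
        const int y0 = 2 * oy, x0 = 2 * ox;
        double best = R_NegInf;
        R_xlen_t bidx = -1;
        for (int dx = 0; dx < 2; ++dx) {
          const int sx = x0 + dx;
          if (sx >= W) continue;
          for (int dy = 0; dy < 2; ++dy) {
            const int sy = y0 + dy;
            if (sy >= H) continue;
            const R_xlen_t idx = base + sy + (R_xlen_t)H * sx;
            if (xp[idx] > best) { best = xp[idx]; bidx = idx; }
          }
        }
        op[o] = best;
        ap[o] = (double)bidx;
      }
    }
  }
  return List::create(_["out"] = out, _["argmax"] = arg,
                      _["Ho"] = Ho, _["Wo"] = Wo);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector dout, NumericVector argmax,
                              double insize) {
  NumericVector dx((R_xlen_t)insize);
  double *gp = dx.begin();
  const double *dp = dout.begin(), *ap = argmax.begin();
  const R_xlen_t n = dout.size();
  for (R_xlen_t i = 0; i < n; ++i) gp[(R_xlen_t)ap[i]] += dp[i];
  return dx;
}
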