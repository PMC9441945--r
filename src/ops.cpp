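// Convolution and pooling kernels for feature maps stored as R arrays with
// dimensions (H, W, C, N), i.e. row index fastest.  Convolutions are expressed
// as im2col + GEMM so that grouped and depthwise cases share one code path.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::uword idx4(arma::uword h, arma::uword w, arma::uword c,
                               arma::uword n, arma::uword H, arma::uword W,
                               arma::uword C) {
  return h + H * (w + W * (c + C * n));
}

// im2col for one sample and one channel group.
// Column p = oh + Ho*ow holds the receptive field, row r = kh + k*kw + k*k*ci.
static void im2col(const double* x, arma::mat& col, arma::uword H, arma::uword W,
                   arma::uword C, arma::uword n, arma::uword c0, arma::uword cg,
                   arma::uword k, arma::uword stride, int pad, arma::uword Ho,
                   arma::uword Wo) {
  col.zeros();
  for (arma::uword ci = 0; ci < cg; ++ci) {
    for (arma::uword kw = 0; kw < k; ++kw) {
      for (arma::uword kh = 0; kh < k; ++kh) {
        arma::uword r = kh + k * kw + k * k * ci;
        for (arma::uword ow = 0; ow < Wo; ++ow) {
          int wi = (int)(ow * stride + kw) - pad;
          if (wi < 0 || wi >= (int)W) continue;
          for (arma::uword oh = 0; oh < Ho; ++oh) {
            int hi = (int)(oh * stride + kh) - pad;
            if (hi < 0 || hi >= (int)H) continue;
            col(r, oh + Ho * ow) =
                x[idx4((arma::uword)hi, (arma::uword)wi, c0 + ci, n, H, W, C)];
          }
        }
      }
    }
  }
}

// scatter-add of a column-form gradient back onto the input (inverse of im2col)
static void col2im(double* gx, const arma::mat& gcol, arma::uword H,
                   arma::uword W, arma::uword C, arma::uword n, arma::uword c0,
                   arma::uword cg, arma::uword k, arma::uword stride, int pad,
                   arma::uword Ho, arma::uword Wo) {
  for (arma::uword ci = 0; ci < cg; ++ci) {
    for (arma::uword kw = 0; kw < k; ++kw) {
      for (arma::uword kh = 0; kh < k; ++kh) {
        arma::uword r = kh + k * kw + k * k * ci;
        for (arma::uword ow = 0; ow < Wo; ++ow) {
          int wi = (int)(ow * stride + kw) - pad;
          if (wi < 0 || wi >= (int)W) continue;
          for (arma::uword oh = 0; oh < Ho; ++oh) {
            int hi = (int)(oh * stride + kh) - pad;
            if (hi < 0 || hi >= (int)H) continue;
            gx[idx4((arma::uword)hi, (arma::uword)wi, c0 + ci, n, H, W, C)] +=
                gcol(r, oh + Ho * ow);
          }
        }
      }
    }
  }
}

static arma::mat weight_mat(const double* wp, arma::uword K, arma::uword og,
                            arma::uword g) {
  arma::mat Wm(og, K);
  for (arma::uword o = 0; o < og; ++o)
    for (arma::uword r = 0; r < K; ++r) Wm(o, r) = wp[r + K * (g * og + o)];
  return Wm;
}

// [[Rcpp::export]]
NumericVector conv2d_fw(NumericVector x, NumericVector w, int stride, int pad,
                        int groups) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  arma::uword H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  arma::uword k = wd[0], cg = wd[2], Cout = wd[3];
  arma::uword G = (arma::uword)groups, og = Cout / G;
  arma::uword Ho = (H + 2 * pad - k) / stride + 1;
  arma::uword Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector y(Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::uword K = k * k * cg, P = Ho * Wo;
  if (k == 1 && stride == 1 && groups == 1) {
    // pointwise convolution: one GEMM per sample over contiguous memory
    arma::mat Wm(const_cast<double*>(w.begin()), C, Cout, false, true);
    for (arma::uword n = 0; n < N; ++n) {
      arma::mat Xm(const_cast<double*>(x.begin()) + (arma::uword)H * W * C * n,
                   H * W, C, false, true);
      arma::mat Ym(y.begin() + (arma::uword)H * W * Cout * n, H * W, Cout,
                   false, true);
      Ym = Xm * Wm;
    }
    return y;
  }
  if (cg == 1 && og == 1) {  // depthwise fast path, no im2col
    for (arma::uword n = 0; n < N; ++n)
      for (arma::uword c = 0; c < C; ++c) {
        const double* xp = x.begin() + idx4(0, 0, c, n, H, W, C);
        const double* wp = w.begin() + K * c;
        double* yp = y.begin() + idx4(0, 0, c, n, Ho, Wo, Cout);
        for (arma::uword ow = 0; ow < Wo; ++ow)
          for (arma::uword oh = 0; oh < Ho; ++oh) {
            double acc = 0;
            for (arma::uword kw = 0; kw < k; ++kw) {
              int wi = (int)(ow * stride + kw) - pad;
              if (wi < 0 || wi >= (int)W) continue;
              for (arma::uword kh = 0; kh < k; ++kh) {
                int hi = (int)(oh * stride + kh) - pad;
                if (hi < 0 || hi >= (int)H) continue;
                acc += wp[kh + k * kw] * xp[hi + H * wi];
              }
            }
            yp[oh + Ho * ow] = acc;
          }
      }
    return y;
  }
  arma::mat col(K, P);
  for (arma::uword n = 0; n < N; ++n) {
    for (arma::uword g = 0; g < G; ++g) {
      im2col(x.begin(), col, H, W, C, n, g * cg, cg, k, stride, pad, Ho, Wo);
      arma::mat Wm = weight_mat(w.begin(), K, og, g);
      arma::mat Y = Wm * col;  // og x P
      for (arma::uword o = 0; o < og; ++o) {
        double* yp = y.begin() + idx4(0, 0, g * og + o, n, Ho, Wo, Cout);
        for (arma::uword p = 0; p < P; ++p) yp[p] = Y(o, p);
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bw(NumericVector x, NumericVector w, NumericVector gy, int stride,
               int pad, int groups) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), gd = gy.attr("dim");
  arma::uword H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  arma::uword k = wd[0], cg = wd[2], Cout = wd[3];
  arma::uword Ho = gd[0], Wo = gd[1];
  arma::uword G = (arma::uword)groups, og = Cout / G;
  arma::uword K = k * k * cg, P = Ho * Wo;
  NumericVector gx(x.size()), gw(w.size());
  gx.attr("dim") = xd;
  gw.attr("dim") = wd;
  if (k == 1 && stride == 1 && groups == 1) {  // pointwise: pure GEMMs
    arma::mat Wm(const_cast<double*>(w.begin()), C, Cout, false, true);
    arma::mat gWm(gw.begin(), C, Cout, false, true);
    for (arma::uword n = 0; n < N; ++n) {
      arma::mat Xm(const_cast<double*>(x.begin()) + (arma::uword)H * W * C * n,
                   H * W, C, false, true);
      arma::mat gYm(const_cast<double*>(gy.begin()) +
                        (arma::uword)Ho * Wo * Cout * n,
                    Ho * Wo, Cout, false, true);
      arma::mat gXm(gx.begin() + (arma::uword)H * W * C * n, H * W, C, false,
                    true);
      gXm = gYm * Wm.t();
      gWm += Xm.t() * gYm;
    }
    return List::create(_["gx"] = gx, _["gw"] = gw);
  }
  if (cg == 1 && og == 1) {  // depthwise fast path
    for (arma::uword n = 0; n < N; ++n)
      for (arma::uword c = 0; c < C; ++c) {
        const double* xp = x.begin() + idx4(0, 0, c, n, H, W, C);
        const double* wp = w.begin() + K * c;
        const double* gp = gy.begin() + idx4(0, 0, c, n, Ho, Wo, Cout);
        double* gxp = gx.begin() + idx4(0, 0, c, n, H, W, C);
        double* gwp = gw.begin() + K * c;
        for (arma::uword ow = 0; ow < Wo; ++ow)
          for (arma::uword oh = 0; oh < Ho; ++oh) {
            double g = gp[oh + Ho * ow];
            if (g == 0) continue;
            for (arma::uword kw = 0; kw < k; ++kw) {
              int wi = (int)(ow * stride + kw) - pad;
              if (wi < 0 || wi >= (int)W) continue;
              for (arma::uword kh = 0; kh < k; ++kh) {
                int hi = (int)(oh * stride + kh) - pad;
                if (hi < 0 || hi >= (int)H) continue;
                gwp[kh + k * kw] += g * xp[hi + H * wi];
                gxp[hi + H * wi] += g * wp[kh + k * kw];
              }
            }
          }
      }
    return List::create(_["gx"] = gx, _["gw"] = gw);
  }
  arma::mat col(K, P), gyM(og, P);
  for (arma::uword n = 0; n < N; ++n) {
    for (arma::uword g = 0; g < G; ++g) {
      im2col(x.begin(), col, H, W, C, n, g * cg, cg, k, stride, pad, Ho, Wo);
      for (arma::uword o = 0; o < og; ++o) {
        const double* gp = gy.begin() + idx4(0, 0, g * og + o, n, Ho, Wo, Cout);
        for (arma::uword p = 0; p < P; ++p) gyM(o, p) = gp[p];
      }
      arma::mat gW = gyM * col.t();  // og x K
      for (arma::uword o = 0; o < og; ++o)
        for (arma::uword r = 0; r < K; ++r) gw[r + K * (g * og + o)] += gW(o, r);
      arma::mat Wm = weight_mat(w.begin(), K, og, g);
      arma::mat gcol = Wm.t() * gyM;  // K x P
      col2im(gx.begin(), gcol, H, W, C, n, g * cg, cg, k, stride, pad, Ho, Wo);
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw);
}

// max pooling with 'same'-style symmetric padding; records argmax (1-based
// linear index into x) so the backward pass is an exact scatter.
// [[Rcpp::export]]
List maxpool_fw(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  arma::uword H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  arma::uword Ho = (H + 2 * pad - k) / stride + 1;
  arma::uword Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector y(Ho * Wo * C * N);
  IntegerVector id(Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  id.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (arma::uword n = 0; n < N; ++n)
    for (arma::uword c = 0; c < C; ++c)
      for (arma::uword ow = 0; ow < Wo; ++ow)
        for (arma::uword oh = 0; oh < Ho; ++oh) {
          double best = -std::numeric_limits<double>::infinity();
          arma::uword bi = 0;
          for (int kw = 0; kw < k; ++kw) {
            int wi = (int)(ow * stride) + kw - pad;
            if (wi < 0 || wi >= (int)W) continue;
            for (int kh = 0; kh < k; ++kh) {
              int hi = (int)(oh * stride) + kh - pad;
              if (hi < 0 || hi >= (int)H) continue;
              arma::uword ii = idx4(hi, wi, c, n, H, W, C);
              if (x[ii] > best) { best = x[ii]; bi = ii; }
            }
          }
          arma::uword oi = idx4(oh, ow, c, n, Ho, Wo, C);
          y[oi] = best;
          id[oi] = (int)bi + 1;
        }
  return List::create(_["y"] = y, _["idx"] = id);
}

// [[Rcpp::export]]
NumericVector maxpool_bw(IntegerVector idx, NumericVector gy, IntegerVector xdim) {
  arma::uword total = (arma::uword)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector gx(total);
  gx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < gy.size(); ++i) gx[idx[i] - 1] += gy[i];
  return gx;
}

// ---- fused per-channel helpers (batch-norm apply, reductions) -----------

// y = a[c] * x + b[c]
// [[Rcpp::export]]
NumericVector ch_scale_shift(NumericVector x, NumericVector a,
                             NumericVector b) {
  IntegerVector xd = x.attr("dim");
  arma::uword HW = (arma::uword)xd[0] * xd[1], C = xd[2], N = xd[3];
  NumericVector y(x.size());
  y.attr("dim") = xd;
  const double* xp = x.begin();
  double* yp = y.begin();
  for (arma::uword n = 0; n < N; ++n)
    for (arma::uword c = 0; c < C; ++c) {
      const double ac = a[c], bc = b[c];
      const double* xs = xp + HW * (c + C * n);
      double* ys = yp + HW * (c + C * n);
      for (arma::uword i = 0; i < HW; ++i) ys[i] = ac * xs[i] + bc;
    }
  return y;
}

// per-channel sums of x and x*y in one pass (y may be R_NilValue)
// [[Rcpp::export]]
List ch_reduce(NumericVector x, Nullable<NumericVector> y) {
  IntegerVector xd = x.attr("dim");
  arma::uword HW = (arma::uword)xd[0] * xd[1], C = xd[2], N = xd[3];
  NumericVector s1(C), s2(C);
  const double* xp = x.begin();
  const double* yp = y.isNotNull() ? NumericVector(y).begin() : nullptr;
  for (arma::uword n = 0; n < N; ++n)
    for (arma::uword c = 0; c < C; ++c) {
      const double* xs = xp + HW * (c + C * n);
      double a = 0, b = 0;
      if (yp) {
        const double* ys = yp + HW * (c + C * n);
        for (arma::uword i = 0; i < HW; ++i) { a += xs[i]; b += xs[i] * ys[i]; }
      } else {
        for (arma::uword i = 0; i < HW; ++i) { a += xs[i]; b += xs[i] * xs[i]; }
      }
      s1[c] += a;
      s2[c] += b;
    }
  return List::create(_["s1"] = s1, _["s2"] = s2);
}

// activations with analytic derivative, fused over the whole array
// kind: 0 none, 1 silu, 2 gelu, 3 leaky_relu(0.1), 4 relu, 5 hswish,
//       6 sigmoid
// [[Rcpp::export]]
NumericVector act_fw(NumericVector x, int kind) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double inv_sqrt2 = 0.7071067811865476;
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    double v = x[i];
    switch (kind) {
      case 0: y[i] = v; break;
      case 1: y[i] = v / (1.0 + std::exp(-v)); break;
      case 2: y[i] = v * 0.5 * (1.0 + std::erf(v * inv_sqrt2)); break;
      case 3: y[i] = v > 0 ? v : 0.1 * v; break;
      case 4: y[i] = v > 0 ? v : 0.0; break;
      case 5: {
        double r = v + 3.0; r = r < 0 ? 0 : (r > 6 ? 6 : r);
        y[i] = v * r / 6.0; break;
      }
      case 6: y[i] = 1.0 / (1.0 + std::exp(-v)); break;
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector act_bw(NumericVector x, NumericVector g, int kind) {
  NumericVector out(x.size());
  out.attr("dim") = x.attr("dim");
  const double inv_sqrt2 = 0.7071067811865476;
  const double inv_sqrt2pi = 0.3989422804014327;
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    double v = x[i], d = 0;
    switch (kind) {
      case 0: d = 1; break;
      case 1: {
        double s = 1.0 / (1.0 + std::exp(-v));
        d = s * (1.0 + v * (1.0 - s)); break;
      }
      case 2: {
        double Phi = 0.5 * (1.0 + std::erf(v * inv_sqrt2));
        d = Phi + v * inv_sqrt2pi * std::exp(-0.5 * v * v); break;
      }
      case 3: d = v > 0 ? 1.0 : 0.1; break;
      case 4: d = v > 0 ? 1.0 : 0.0; break;
      case 5: d = v <= -3 ? 0 : (v >= 3 ? 1.0 : (2.0 * v + 3.0) / 6.0); break;
      case 6: {
        double s = 1.0 / (1.0 + std::exp(-v));
        d = s * (1.0 - s); break;
      }
    }
    out[i] = g[i] * d;
  }
  return out;
}

// fused batch-norm backward: given the gradient after the affine stage and
// the pre-normalisation activations, returns per-channel reductions
// (s1 = sum g, s2 = sum g * xhat) and the gradient w.r.t. the conv output,
// recomputing xhat on the fly so the forward pass never materialises it.
// [[Rcpp::export]]
List bn_bwd(NumericVector g1, NumericVector z0, NumericVector mu,
            NumericVector ivar, NumericVector gamma, bool training) {
  IntegerVector xd = g1.attr("dim");
  arma::uword HW = (arma::uword)xd[0] * xd[1], C = xd[2], N = xd[3];
  NumericVector s1(C), s2(C), gz0(g1.size());
  gz0.attr("dim") = xd;
  const double* gp = g1.begin();
  const double* zp = z0.begin();
  for (arma::uword n = 0; n < N; ++n)
    for (arma::uword c = 0; c < C; ++c) {
      const double m = mu[c], iv = ivar[c];
      const double* gs = gp + HW * (c + C * n);
      const double* zs = zp + HW * (c + C * n);
      double a = 0, b = 0;
      for (arma::uword i = 0; i < HW; ++i) {
        a += gs[i];
        b += gs[i] * (zs[i] - m) * iv;
      }
      s1[c] += a;
      s2[c] += b;
    }
  const double cnt = (double)(HW * N);
  double* op = gz0.begin();
  for (arma::uword n = 0; n < N; ++n)
    for (arma::uword c = 0; c < C; ++c) {
      const double m = mu[c], iv = ivar[c], ga = gamma[c];
      const double k1 = training ? s1[c] / cnt : 0.0;
      const double k2 = training ? s2[c] / cnt : 0.0;
      const double* gs = gp + HW * (c + C * n);
      const double* zs = zp + HW * (c + C * n);
      double* os = op + HW * (c + C * n);
      for (arma::uword i = 0; i < HW; ++i)
        os[i] = ga * iv * (gs[i] - k1 - (zs[i] - m) * iv * k2);
    }
  return List::create(_["gz0"] = gz0, _["s1"] = s1, _["s2"] = s2);
}
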