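// Low-level numerical kernels for the segmentation network.
//
// Tensor layout convention (shared with the R side): a feature-map batch is a
// numeric array with dim c(H, W, C, N), column-major, so the linear offset of
// element (h, w, c, n) is h + H*(w + W*(c + C*n)), all indices 0-based here.
//
// Convolution weights have dim c(kh, kw, Cin, Cout); depthwise weights
// c(kh, kw, C).  Convolutions are lowered to GEMM via an im2col buffer of
// shape (Ho*Wo) x (kh*kw*Cin) so that both the forward product and the two
// backward products are single BLAS calls per image.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int conv_out_dim(int in, int k, int stride, int pad, int dil) {
  return (in + 2 * pad - dil * (k - 1) - 1) / stride + 1;
}

// Fill colT (M x K), M = Ho*Wo, K = kh*kw*Cin; row q = ho + Ho*wo,
// column r = i + kh*(j + kw*c) which matches the native weight layout.
static void im2col_t(const double* x, int H, int W, int C,
                     int kh, int kw, int stride, int pad, int dil,
                     int Ho, int Wo, arma::mat& colT) {
  const int M = Ho * Wo;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int r = i + kh * (j + kw * c);
        double* dst = colT.colptr(r);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + j * dil;
          double* dq = dst + (size_t)Ho * wo;
          if (wi < 0 || wi >= W) {
            std::fill(dq, dq + Ho, 0.0);
            continue;
          }
          const double* xcol = xc + (size_t)H * wi;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * stride - pad + i * dil;
            dq[ho] = (hi >= 0 && hi < H) ? xcol[hi] : 0.0;
          }
        }
      }
    }
  }
}

// Scatter-add of colT-shaped gradient back onto the input image.
static void col2im_t(const arma::mat& colTgrad, double* dx, int H, int W, int C,
                     int kh, int kw, int stride, int pad, int dil,
                     int Ho, int Wo) {
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)H * W * c;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int r = i + kh * (j + kw * c);
        const double* src = colTgrad.colptr(r);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + j * dil;
          if (wi < 0 || wi >= W) continue;
          double* xcol = xc + (size_t)H * wi;
          const double* sq = src + (size_t)Ho * wo;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * stride - pad + i * dil;
            if (hi >= 0 && hi < H) xcol[hi] += sq[ho];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cs_conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                            int stride, int pad, int dil) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: input has %d channels, weight expects %d", C, Cin);
  const int Ho = conv_out_dim(H, kh, stride, pad, dil);
  const int Wo = conv_out_dim(W, kw, stride, pad, dil);
  if (Ho <= 0 || Wo <= 0) stop("conv2d: non-positive output size");
  const int K = kh * kw * Cin, M = Ho * Wo;
  NumericVector y(Rf_allocVector(REALSXP, (R_xlen_t)M * Cout * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  const arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  const bool has_b = b.size() > 0;
  arma::mat colT(M, K);
  const bool pointwise = (kh == 1 && kw == 1 && stride == 1 && pad == 0);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)H * W * C * n;
    arma::mat Yn(y.begin() + (size_t)M * Cout * n, M, Cout, false, true);
    if (pointwise) {
      const arma::mat Xn(const_cast<double*>(xn), M, C, false, true);
      Yn = Xn * Wm;
    } else {
      im2col_t(xn, H, W, C, kh, kw, stride, pad, dil, Ho, Wo, colT);
      Yn = colT * Wm;
    }
    if (has_b)
      for (int o = 0; o < Cout; ++o) Yn.col(o) += b[o];
  }
  return y;
}

// [[Rcpp::export]]
List cs_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                   int stride, int pad, int dil, bool need_dx, bool need_db) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int Ho = yd[0], Wo = yd[1];
  const int K = kh * kw * C, M = Ho * Wo;
  const arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);

  NumericVector dw(Rf_allocVector(REALSXP, (R_xlen_t)K * Cout));
  dw.attr("dim") = wd;
  arma::mat dWm(dw.begin(), K, Cout, false, true);
  dWm.zeros();
  NumericVector dx;
  if (need_dx) {
    dx = NumericVector(Rf_allocVector(REALSXP, (R_xlen_t)H * W * C * N));
    dx.attr("dim") = xd;
    std::fill(dx.begin(), dx.end(), 0.0);
  }
  NumericVector db(Cout);

  const bool pointwise = (kh == 1 && kw == 1 && stride == 1 && pad == 0);
  arma::mat colT(M, K), colTgrad;
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)H * W * C * n;
    const arma::mat dYn(const_cast<double*>(dy.begin()) + (size_t)M * Cout * n,
                        M, Cout, false, true);
    if (pointwise) {
      const arma::mat Xn(const_cast<double*>(xn), M, C, false, true);
      dWm += Xn.t() * dYn;
      if (need_dx) {
        arma::mat dXn(dx.begin() + (size_t)H * W * C * n, M, C, false, true);
        dXn += dYn * Wm.t();
      }
    } else {
      im2col_t(xn, H, W, C, kh, kw, stride, pad, dil, Ho, Wo, colT);
      dWm += colT.t() * dYn;
      if (need_dx) {
        colTgrad = dYn * Wm.t();
        col2im_t(colTgrad, dx.begin() + (size_t)H * W * C * n,
                 H, W, C, kh, kw, stride, pad, dil, Ho, Wo);
      }
    }
    if (need_db)
      for (int o = 0; o < Cout; ++o) db[o] += arma::accu(dYn.col(o));
  }
  return List::create(_["dx"] = need_dx ? (SEXP)dx : R_NilValue,
                      _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
NumericVector cs_dwconv_fwd(NumericVector x, NumericVector w,
                            int stride, int pad, int dil) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1];
  if (wd[2] != C) stop("dwconv: channel mismatch (%d vs %d)", C, (int)wd[2]);
  const int Ho = conv_out_dim(H, kh, stride, pad, dil);
  const int Wo = conv_out_dim(W, kw, stride, pad, dil);
  NumericVector y(Rf_allocVector(REALSXP, (R_xlen_t)Ho * Wo * C * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  std::fill(y.begin(), y.end(), 0.0);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      double* yc = y.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      const double* wc = w.begin() + (size_t)kh * kw * c;
      for (int j = 0; j < kw; ++j)
        for (int i = 0; i < kh; ++i) {
          const double wij = wc[i + kh * j];
          if (wij == 0.0) continue;
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * stride - pad + j * dil;
            if (wi < 0 || wi >= W) continue;
            const double* xcol = xc + (size_t)H * wi;
            double* ycol = yc + (size_t)Ho * wo;
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * stride - pad + i * dil;
              if (hi >= 0 && hi < H) ycol[ho] += wij * xcol[hi];
            }
          }
        }
    }
  return y;
}

// [[Rcpp::export]]
List cs_dwconv_bwd(NumericVector x, NumericVector w, NumericVector dy,
                   int stride, int pad, int dil) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1];
  const int Ho = yd[0], Wo = yd[1];
  NumericVector dx(Rf_allocVector(REALSXP, (R_xlen_t)H * W * C * N));
  dx.attr("dim") = xd;
  std::fill(dx.begin(), dx.end(), 0.0);
  NumericVector dw(Rf_allocVector(REALSXP, (R_xlen_t)kh * kw * C));
  dw.attr("dim") = wd;
  std::fill(dw.begin(), dw.end(), 0.0);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      const double* gc = dy.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      double* dxc = dx.begin() + (size_t)H * W * (c + (size_t)C * n);
      double* dwc = dw.begin() + (size_t)kh * kw * c;
      for (int j = 0; j < kw; ++j)
        for (int i = 0; i < kh; ++i) {
          const double wij = w[i + kh * (j + kw * c)];
          double acc = 0.0;
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * stride - pad + j * dil;
            if (wi < 0 || wi >= W) continue;
            const double* xcol = xc + (size_t)H * wi;
            double* dxcol = dxc + (size_t)H * wi;
            const double* gcol = gc + (size_t)Ho * wo;
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * stride - pad + i * dil;
              if (hi < 0 || hi >= H) continue;
              acc += gcol[ho] * xcol[hi];
              dxcol[hi] += gcol[ho] * wij;
            }
          }
          dwc[i + kh * j] += acc;
        }
    }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// Batch normalisation over (H, W, N) per channel.
// [[Rcpp::export]]
List cs_bn_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
               NumericVector rmean, NumericVector rvar,
               double momentum, double eps, bool training) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t plane = (size_t)H * W;
  const double Mtot = (double)plane * N;
  NumericVector y(Rf_allocVector(REALSXP, (R_xlen_t)plane * C * N));
  y.attr("dim") = xd;
  NumericVector mean(C), invstd(C), new_rmean(clone(rmean)), new_rvar(clone(rvar));
  for (int c = 0; c < C; ++c) {
    double mu, is;
    if (training) {
      double s = 0.0, s2 = 0.0;
      for (int n = 0; n < N; ++n) {
        const double* xc = x.begin() + plane * (c + (size_t)C * n);
        for (size_t k = 0; k < plane; ++k) { s += xc[k]; s2 += xc[k] * xc[k]; }
      }
      mu = s / Mtot;
      double var = s2 / Mtot - mu * mu;
      if (var < 0) var = 0;
      is = 1.0 / std::sqrt(var + eps);
      const double ub = Mtot > 1 ? var * Mtot / (Mtot - 1.0) : var;
      new_rmean[c] = (1.0 - momentum) * rmean[c] + momentum * mu;
      new_rvar[c] = (1.0 - momentum) * rvar[c] + momentum * ub;
    } else {
      mu = rmean[c];
      is = 1.0 / std::sqrt(rvar[c] + eps);
    }
    mean[c] = mu; invstd[c] = is;
    const double a = gamma[c] * is, b0 = beta[c] - a * mu;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + plane * (c + (size_t)C * n);
      double* yc = y.begin() + plane * (c + (size_t)C * n);
      for (size_t k = 0; k < plane; ++k) yc[k] = a * xc[k] + b0;
    }
  }
  return List::create(_["y"] = y, _["mean"] = mean, _["invstd"] = invstd,
                      _["rmean"] = new_rmean, _["rvar"] = new_rvar);
}

// [[Rcpp::export]]
List cs_bn_bwd(NumericVector x, NumericVector gamma, NumericVector dy,
               NumericVector mean, NumericVector invstd) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t plane = (size_t)H * W;
  const double Mtot = (double)plane * N;
  NumericVector dx(Rf_allocVector(REALSXP, (R_xlen_t)plane * C * N));
  dx.attr("dim") = xd;
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double mu = mean[c], is = invstd[c];
    double sg = 0.0, sgx = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + plane * (c + (size_t)C * n);
      const double* gc = dy.begin() + plane * (c + (size_t)C * n);
      for (size_t k = 0; k < plane; ++k) {
        sg += gc[k];
        sgx += gc[k] * (xc[k] - mu) * is;
      }
    }
    dgamma[c] = sgx; dbeta[c] = sg;
    const double a = gamma[c] * is / Mtot;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + plane * (c + (size_t)C * n);
      const double* gc = dy.begin() + plane * (c + (size_t)C * n);
      double* dc = dx.begin() + plane * (c + (size_t)C * n);
      for (size_t k = 0; k < plane; ++k) {
        const double xhat = (xc[k] - mu) * is;
        dc[k] = a * (Mtot * gc[k] - sg - xhat * sgx);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// Bilinear resampling with half-pixel centre alignment.
static void bilinear_weights(int out, int in, std::vector<int>& i0,
                             std::vector<int>& i1, std::vector<double>& w1) {
  const double scale = (double)in / out;
  i0.resize(out); i1.resize(out); w1.resize(out);
  for (int o = 0; o < out; ++o) {
    double src = (o + 0.5) * scale - 0.5;
    if (src < 0) src = 0;
    if (src > in - 1) src = in - 1;
    const int lo = (int)std::floor(src);
    i0[o] = lo;
    i1[o] = std::min(lo + 1, in - 1);
    w1[o] = src - lo;
  }
}

// [[Rcpp::export]]
NumericVector cs_bilinear_fwd(NumericVector x, int Ho, int Wo) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  std::vector<int> h0, h1, w0, w1v;
  std::vector<double> hw, ww;
  bilinear_weights(Ho, H, h0, h1, hw);
  bilinear_weights(Wo, W, w0, w1v, ww);
  NumericVector y(Rf_allocVector(REALSXP, (R_xlen_t)Ho * Wo * C * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      double* yc = y.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        const double* cl = xc + (size_t)H * w0[wo];
        const double* cr = xc + (size_t)H * w1v[wo];
        const double bw = ww[wo];
        double* ycol = yc + (size_t)Ho * wo;
        for (int ho = 0; ho < Ho; ++ho) {
          const double top = cl[h0[ho]] * (1 - bw) + cr[h0[ho]] * bw;
          const double bot = cl[h1[ho]] * (1 - bw) + cr[h1[ho]] * bw;
          ycol[ho] = top * (1 - hw[ho]) + bot * hw[ho];
        }
      }
    }
  return y;
}

// [[Rcpp::export]]
NumericVector cs_bilinear_bwd(NumericVector dy, int H, int W) {
  IntegerVector yd = dy.attr("dim");
  const int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  std::vector<int> h0, h1, w0, w1v;
  std::vector<double> hw, ww;
  bilinear_weights(Ho, H, h0, h1, hw);
  bilinear_weights(Wo, W, w0, w1v, ww);
  NumericVector dx(Rf_allocVector(REALSXP, (R_xlen_t)H * W * C * N));
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  std::fill(dx.begin(), dx.end(), 0.0);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* gc = dy.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      double* xc = dx.begin() + (size_t)H * W * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        double* cl = xc + (size_t)H * w0[wo];
        double* cr = xc + (size_t)H * w1v[wo];
        const double bw = ww[wo];
        const double* gcol = gc + (size_t)Ho * wo;
        for (int ho = 0; ho < Ho; ++ho) {
          const double g = gcol[ho], a = hw[ho];
          cl[h0[ho]] += g * (1 - a) * (1 - bw);
          cr[h0[ho]] += g * (1 - a) * bw;
          cl[h1[ho]] += g * a * (1 - bw);
          cr[h1[ho]] += g * a * bw;
        }
      }
    }
  return dx;
}

// Global average pool: (H,W,C,N) -> C x N matrix.
// [[Rcpp::export]]
NumericMatrix cs_gap_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t plane = (size_t)H * W;
  NumericMatrix s(C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + plane * (c + (size_t)C * n);
      double acc = 0.0;
      for (size_t k = 0; k < plane; ++k) acc += xc[k];
      s(c, n) = acc / (double)plane;
    }
  return s;
}

// Per-pixel softmax cross-entropy; target is H x W x N integer labels
// (0-based), -1 = ignore.  Returns mean loss over scored pixels and the
// gradient w.r.t. logits (already divided by the pixel count).
// [[Rcpp::export]]
List cs_softmax_ce(NumericVector logits, IntegerVector target) {
  IntegerVector xd = logits.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t plane = (size_t)H * W;
  NumericVector dx(Rf_allocVector(REALSXP, (R_xlen_t)plane * C * N));
  dx.attr("dim") = xd;
  std::fill(dx.begin(), dx.end(), 0.0);
  double loss = 0.0;
  R_xlen_t count = 0;
  std::vector<double> p(C);
  for (int n = 0; n < N; ++n) {
    const double* xn = logits.begin() + plane * C * (size_t)n;
    double* dn = dx.begin() + plane * C * (size_t)n;
    const int* tn = target.begin() + plane * (size_t)n;
    for (size_t k = 0; k < plane; ++k) {
      const int t = tn[k];
      if (t < 0) continue;
      double mx = -DBL_MAX;
      for (int c = 0; c < C; ++c) mx = std::max(mx, xn[k + plane * c]);
      double z = 0.0;
      for (int c = 0; c < C; ++c) { p[c] = std::exp(xn[k + plane * c] - mx); z += p[c]; }
      loss += -(std::log(p[t]) - std::log(z));
      for (int c = 0; c < C; ++c) dn[k + plane * c] = p[c] / z;
      dn[k + plane * t] -= 1.0;
      ++count;
    }
  }
  if (count == 0) stop("cross-entropy: no scored pixels");
  const double inv = 1.0 / (double)count;
  for (R_xlen_t i = 0; i < dx.size(); ++i) dx[i] *= inv;
  return List::create(_["loss"] = loss * inv, _["dx"] = dx);
}

// Per-pixel argmax over channels -> H x W x N integer labels (0-based).
// Ties break toward the lower class index.
// [[Rcpp::export]]
IntegerVector cs_channel_argmax(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t plane = (size_t)H * W;
  IntegerVector lab(Rf_allocVector(INTSXP, (R_xlen_t)plane * N));
  lab.attr("dim") = IntegerVector::create(H, W, N);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + plane * C * (size_t)n;
    int* ln = lab.begin() + plane * (size_t)n;
    for (size_t k = 0; k < plane; ++k) {
      int best = 0;
      double bv = xn[k];
      for (int c = 1; c < C; ++c) {
        const double v = xn[k + plane * c];
        if (v > bv) { bv = v; best = c; }
      }
      ln[k] = best;
    }
  }
  return lab;
}
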