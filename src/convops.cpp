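// Low-level tensor kernels for the micro-expert networks.
//
// Tensors are R arrays with dim (H, W, C, N), column-major, so the flat
// index of (h, w, c, n) is h + H*(w + W*(c + C*n)).  Convolution is the
// CNN convention (cross-correlation); "same" spatial geometry is kept by
// mirror (reflect) padding, with the mirror axis on the border pixel.
//
// The forward/backward pair below is the computational core of training:
// im2col + GEMM via Armadillo, grouped to cover standard, depthwise
// (groups == in_channels) and pointwise (1x1) convolutions.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int reflect_idx(int i, int n) {
  // mirror without edge repetition: -1 -> 1, n -> n-2
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * n - 2 - i;
  }
  return i;
}

struct ConvGeom {
  int H, W, C, N, KH, KW, Cg, Cout, Coutg, G;
  int stride, dil, Ho, Wo, pt, pl;
};

static ConvGeom conv_geom(const IntegerVector& xd, const IntegerVector& wd,
                          int stride, int dilation, int groups) {
  ConvGeom g;
  g.H = xd[0]; g.W = xd[1]; g.C = xd[2]; g.N = xd[3];
  g.KH = wd[0]; g.KW = wd[1]; g.Cg = wd[2]; g.Cout = wd[3];
  g.G = groups; g.Coutg = g.Cout / groups;
  g.stride = stride; g.dil = dilation;
  g.Ho = (g.H + stride - 1) / stride;
  g.Wo = (g.W + stride - 1) / stride;
  int span_h = (g.KH - 1) * dilation + 1;
  int span_w = (g.KW - 1) * dilation + 1;
  int pad_h = std::max(0, (g.Ho - 1) * stride + span_h - g.H);
  int pad_w = std::max(0, (g.Wo - 1) * stride + span_w - g.W);
  g.pt = pad_h / 2; g.pl = pad_w / 2;
  return g;
}

// fill the im2col matrix for sample n, group gr: (KH*KW*Cg) x (Ho*Wo)
static void im2col_fill(const double* x, const ConvGeom& g, int n, int gr,
                        arma::mat& col) {
  const int HW = g.H * g.W;
  for (int ci = 0; ci < g.Cg; ++ci) {
    const int c = gr * g.Cg + ci;
    const double* xc = x + (size_t)HW * (c + (size_t)g.C * n);
    for (int kw = 0; kw < g.KW; ++kw) {
      for (int kh = 0; kh < g.KH; ++kh) {
        const int e = kh + g.KH * (kw + g.KW * ci);
        for (int wo = 0; wo < g.Wo; ++wo) {
          const int wi = reflect_idx(wo * g.stride - g.pl + kw * g.dil, g.W);
          for (int ho = 0; ho < g.Ho; ++ho) {
            const int hi = reflect_idx(ho * g.stride - g.pt + kh * g.dil, g.H);
            col(e, ho + g.Ho * wo) = xc[hi + g.H * wi];
          }
        }
      }
    }
  }
}

// fast path: pointwise (1x1, stride 1, groups 1) convolution is a GEMM on
// the (HW x C) sample slab, no im2col copy needed
static bool is_pointwise(const ConvGeom& g) {
  return g.KH == 1 && g.KW == 1 && g.stride == 1 && g.G == 1;
}

// fast path: depthwise 3x3 stride-1 convolution via direct loops with an
// interior/border split (reflect indexing only at the border)
static bool is_depthwise3(const ConvGeom& g) {
  return g.KH == 3 && g.KW == 3 && g.stride == 1 && g.Cg == 1 &&
         g.Coutg == 1 && g.H > 2 * g.dil && g.W > 2 * g.dil;
}

static void dw3_fwd_channel(const double* xc, double* yc, const double* k,
                            double bias, int H, int W, int dil) {
  // k is the 3x3 kernel in column-major (kh fastest)
  for (int w = 0; w < W; ++w) {
    const bool win = (w >= dil && w < W - dil);
    const int wm = win ? w - dil : reflect_idx(w - dil, W);
    const int wp = win ? w + dil : reflect_idx(w + dil, W);
    const double* cm = xc + (size_t)H * wm;
    const double* c0 = xc + (size_t)H * w;
    const double* cp = xc + (size_t)H * wp;
    double* yo = yc + (size_t)H * w;
    for (int h = 0; h < H; ++h) {
      int hm = h - dil, hp = h + dil;
      if (hm < 0) hm = -hm;
      if (hp >= H) hp = 2 * H - 2 - hp;
      yo[h] = bias +
        cm[hm] * k[0] + cm[h] * k[1] + cm[hp] * k[2] +
        c0[hm] * k[3] + c0[h] * k[4] + c0[hp] * k[5] +
        cp[hm] * k[6] + cp[h] * k[7] + cp[hp] * k[8];
    }
  }
}

static void dw3_bwd_channel(const double* xc, const double* gyc, const double* k,
                            double* gxc, double* gk, double* gb,
                            int H, int W, int dil) {
  for (int w = 0; w < W; ++w) {
    const int wm = reflect_idx(w - dil, W), wp = reflect_idx(w + dil, W);
    const double* cm = xc + (size_t)H * wm;
    const double* c0 = xc + (size_t)H * w;
    const double* cp = xc + (size_t)H * wp;
    double* gm = gxc + (size_t)H * wm;
    double* g0 = gxc + (size_t)H * w;
    double* gp = gxc + (size_t)H * wp;
    const double* gy = gyc + (size_t)H * w;
    for (int h = 0; h < H; ++h) {
      int hm = h - dil, hp = h + dil;
      if (hm < 0) hm = -hm;
      if (hp >= H) hp = 2 * H - 2 - hp;
      const double g = gy[h];
      *gb += g;
      gk[0] += g * cm[hm]; gk[1] += g * cm[h]; gk[2] += g * cm[hp];
      gk[3] += g * c0[hm]; gk[4] += g * c0[h]; gk[5] += g * c0[hp];
      gk[6] += g * cp[hm]; gk[7] += g * cp[h]; gk[8] += g * cp[hp];
      gm[hm] += g * k[0]; gm[h] += g * k[1]; gm[hp] += g * k[2];
      g0[hm] += g * k[3]; g0[h] += g * k[4]; g0[hp] += g * k[5];
      gp[hm] += g * k[6]; gp[h] += g * k[7]; gp[hp] += g * k[8];
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w,
                             Nullable<NumericVector> bias,
                             int stride, int dilation, int groups) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  ConvGeom g = conv_geom(xd, wd, stride, dilation, groups);
  if (g.C != g.Cg * g.G) stop("channel/group mismatch");
  std::vector<double> bv0(g.Cout, 0.0);
  if (bias.isNotNull()) {
    NumericVector b(bias);
    for (int i = 0; i < g.Cout; ++i) bv0[i] = b[i];
  }
  if (is_pointwise(g)) {
    NumericVector y(ptrdiff_t(g.H) * g.W * g.Cout * g.N);
    y.attr("dim") = IntegerVector::create(g.H, g.W, g.Cout, g.N);
    const int HW = g.H * g.W;
    arma::mat Wm(const_cast<double*>(w.begin()), g.C, g.Cout, false, true);
    for (int n = 0; n < g.N; ++n) {
      arma::mat Xn(const_cast<double*>(x.begin()) + (size_t)HW * g.C * n,
                   HW, g.C, false, true);
      arma::mat Yn(y.begin() + (size_t)HW * g.Cout * n, HW, g.Cout, false, true);
      Yn = Xn * Wm;
      for (int c = 0; c < g.Cout; ++c) Yn.col(c) += bv0[c];
    }
    return y;
  }
  if (is_depthwise3(g)) {
    NumericVector y(x.size());
    y.attr("dim") = xd;
    const int HW = g.H * g.W;
    for (int n = 0; n < g.N; ++n)
      for (int c = 0; c < g.C; ++c)
        dw3_fwd_channel(x.begin() + (size_t)HW * (c + (size_t)g.C * n),
                        y.begin() + (size_t)HW * (c + (size_t)g.C * n),
                        w.begin() + 9 * c, bv0[c], g.H, g.W, g.dil);
    return y;
  }
  NumericVector y(ptrdiff_t(g.Ho) * g.Wo * g.Cout * g.N);
  y.attr("dim") = IntegerVector::create(g.Ho, g.Wo, g.Cout, g.N);

  const int E = g.KH * g.KW * g.Cg, P = g.Ho * g.Wo;
  arma::mat col(E, P);
  arma::mat Wm(const_cast<double*>(w.begin()), E, g.Cout, false, true);
  const double* xp = x.begin();
  double* yp = y.begin();
  std::vector<double> bv(g.Cout, 0.0);
  if (bias.isNotNull()) {
    NumericVector b(bias);
    for (int i = 0; i < g.Cout; ++i) bv[i] = b[i];
  }
  for (int n = 0; n < g.N; ++n) {
    for (int gr = 0; gr < g.G; ++gr) {
      im2col_fill(xp, g, n, gr, col);
      arma::mat Y = Wm.cols(gr * g.Coutg, (gr + 1) * g.Coutg - 1).t() * col; // Coutg x P
      for (int co = 0; co < g.Coutg; ++co) {
        const int c = gr * g.Coutg + co;
        double* dst = yp + (size_t)P * (c + (size_t)g.Cout * n);
        const double bc = bv[c];
        for (int p = 0; p < P; ++p) dst[p] = Y(co, p) + bc;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                    int stride, int dilation, int groups, bool need_gx) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  ConvGeom g = conv_geom(xd, wd, stride, dilation, groups);
  const int E = g.KH * g.KW * g.Cg, P = g.Ho * g.Wo;

  NumericVector gw(w.size());
  gw.attr("dim") = wd;
  NumericVector gb(g.Cout);
  NumericVector gx(need_gx ? x.size() : 0);
  if (need_gx) gx.attr("dim") = xd;

  if (is_pointwise(g)) {
    const int HW = g.H * g.W;
    arma::mat Wm(const_cast<double*>(w.begin()), g.C, g.Cout, false, true);
    arma::mat Gwm(gw.begin(), g.C, g.Cout, false, true);
    for (int n = 0; n < g.N; ++n) {
      arma::mat Xn(const_cast<double*>(x.begin()) + (size_t)HW * g.C * n,
                   HW, g.C, false, true);
      arma::mat Gyn(const_cast<double*>(gy.begin()) + (size_t)HW * g.Cout * n,
                    HW, g.Cout, false, true);
      Gwm += Xn.t() * Gyn;
      for (int c = 0; c < g.Cout; ++c) gb[c] += arma::accu(Gyn.col(c));
      if (need_gx) {
        arma::mat Gxn(gx.begin() + (size_t)HW * g.C * n, HW, g.C, false, true);
        Gxn += Gyn * Wm.t();
      }
    }
    return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
  }
  if (is_depthwise3(g) && need_gx) {
    const int HW = g.H * g.W;
    for (int n = 0; n < g.N; ++n)
      for (int c = 0; c < g.C; ++c)
        dw3_bwd_channel(x.begin() + (size_t)HW * (c + (size_t)g.C * n),
                        gy.begin() + (size_t)HW * (c + (size_t)g.C * n),
                        w.begin() + 9 * c,
                        gx.begin() + (size_t)HW * (c + (size_t)g.C * n),
                        gw.begin() + 9 * c, &gb[c], g.H, g.W, g.dil);
    return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
  }

  arma::mat col(E, P);
  arma::mat Wm(const_cast<double*>(w.begin()), E, g.Cout, false, true);
  arma::mat Gwm(gw.begin(), E, g.Cout, false, true);
  const double* xp = x.begin();
  const double* gyp = gy.begin();
  double* gxp = need_gx ? gx.begin() : nullptr;

  arma::mat Gy(g.Coutg, P);
  for (int n = 0; n < g.N; ++n) {
    for (int gr = 0; gr < g.G; ++gr) {
      im2col_fill(xp, g, n, gr, col);
      for (int co = 0; co < g.Coutg; ++co) {
        const int c = gr * g.Coutg + co;
        const double* src = gyp + (size_t)P * (c + (size_t)g.Cout * n);
        double s = 0.0;
        for (int p = 0; p < P; ++p) { Gy(co, p) = src[p]; s += src[p]; }
        gb[c] += s;
      }
      Gwm.cols(gr * g.Coutg, (gr + 1) * g.Coutg - 1) += col * Gy.t();
      if (need_gx) {
        arma::mat colg = Wm.cols(gr * g.Coutg, (gr + 1) * g.Coutg - 1) * Gy; // E x P
        // col2im with reflect accumulation
        const int HW = g.H * g.W;
        for (int ci = 0; ci < g.Cg; ++ci) {
          const int c = gr * g.Cg + ci;
          double* gxc = gxp + (size_t)HW * (c + (size_t)g.C * n);
          for (int kw = 0; kw < g.KW; ++kw) {
            for (int kh = 0; kh < g.KH; ++kh) {
              const int e = kh + g.KH * (kw + g.KW * ci);
              for (int wo = 0; wo < g.Wo; ++wo) {
                const int wi = reflect_idx(wo * g.stride - g.pl + kw * g.dil, g.W);
                for (int ho = 0; ho < g.Ho; ++ho) {
                  const int hi = reflect_idx(ho * g.stride - g.pt + kh * g.dil, g.H);
                  gxc[hi + g.H * wi] += colg(e, ho + g.Ho * wo);
                }
              }
            }
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y(ptrdiff_t(Ho) * Wo * C * N);
  IntegerVector idx(y.size());
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t base = (size_t)H * W * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          // ties broken by first index in column-major (row-major doc order equivalent for 2x2)
          size_t i00 = base + (2 * ho) + (size_t)H * (2 * wo);
          size_t best = i00; double bv = xp[i00];
          size_t i10 = i00 + 1, i01 = i00 + H, i11 = i00 + H + 1;
          if (xp[i10] > bv) { bv = xp[i10]; best = i10; }
          if (xp[i01] > bv) { bv = xp[i01]; best = i01; }
          if (xp[i11] > bv) { bv = xp[i11]; best = i11; }
          yp[o] = bv; ip[o] = (int)best; ++o;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(IntegerVector idx, NumericVector gy,
                               IntegerVector xdim) {
  NumericVector gx((ptrdiff_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  gx.attr("dim") = xdim;
  const double* gp = gy.begin();
  const int* ip = idx.begin();
  double* gxp = gx.begin();
  const R_xlen_t n = gy.size();
  for (R_xlen_t i = 0; i < n; ++i) gxp[ip[i]] += gp[i];
  return gx;
}

// [[Rcpp::export]]
NumericMatrix cpp_bilinear_resize(NumericMatrix x, int oh, int ow) {
  const int h = x.nrow(), w = x.ncol();
  NumericMatrix y(oh, ow);
  const double sh = (double)h / oh, sw = (double)w / ow;
  for (int j = 0; j < ow; ++j) {
    double fx = (j + 0.5) * sw - 0.5;
    int x0 = (int)std::floor(fx);
    double dx = fx - x0;
    int x1 = std::min(w - 1, std::max(0, x0 + 1));
    x0 = std::min(w - 1, std::max(0, x0));
    for (int i = 0; i < oh; ++i) {
      double fy = (i + 0.5) * sh - 0.5;
      int y0 = (int)std::floor(fy);
      double dy = fy - y0;
      int y1 = std::min(h - 1, std::max(0, y0 + 1));
      y0 = std::min(h - 1, std::max(0, y0));
      y(i, j) = (1 - dy) * ((1 - dx) * x(y0, x0) + dx * x(y0, x1)) +
                dy * ((1 - dx) * x(y1, x0) + dx * x(y1, x1));
    }
  }
  return y;
}
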