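// Per-channel arithmetic for batch norm, global average pooling and
// channel gating on (H, W, C, N) arrays, fused into single passes to
// avoid R-level broadcast temporaries in the training loop.

#include <Rcpp.h>
using namespace Rcpp;

static inline void get_dims(const NumericVector& x, int& HW, int& C, int& N) {
  IntegerVector d = x.attr("dim");
  HW = d[0] * d[1]; C = d[2]; N = d[3];
}

// y = a[c] * x + b[c]
// [[Rcpp::export]]
NumericVector cpp_chan_affine_c(NumericVector x, NumericVector a, NumericVector b) {
  int HW, C, N; get_dims(x, HW, C, N);
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* xp = x.begin(); double* yp = y.begin();
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double ac = a[c], bc = b[c];
      for (int i = 0; i < HW; ++i, ++o) yp[o] = ac * xp[o] + bc;
    }
  return y;
}

// per-channel sums over H, W and N of x (or x*y when y given)
// [[Rcpp::export]]
NumericVector cpp_chan_sums_c(NumericVector x, Nullable<NumericVector> y) {
  int HW, C, N; get_dims(x, HW, C, N);
  NumericVector out(C);
  const double* xp = x.begin();
  if (y.isNotNull()) {
    NumericVector yy(y);
    const double* yp = yy.begin();
    size_t o = 0;
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < C; ++c) {
        double s = 0;
        for (int i = 0; i < HW; ++i, ++o) s += xp[o] * yp[o];
        out[c] += s;
      }
  } else {
    size_t o = 0;
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < C; ++c) {
        double s = 0;
        for (int i = 0; i < HW; ++i, ++o) s += xp[o];
        out[c] += s;
      }
  }
  return out;
}

// C x N matrix of sums over H, W of x (or x*y)
// [[Rcpp::export]]
NumericMatrix cpp_chan_sums_cn(NumericVector x, Nullable<NumericVector> y) {
  int HW, C, N; get_dims(x, HW, C, N);
  NumericMatrix out(C, N);
  const double* xp = x.begin();
  const double* yp = nullptr;
  NumericVector yy;
  if (y.isNotNull()) { yy = NumericVector(y); yp = yy.begin(); }
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double s = 0;
      if (yp) for (int i = 0; i < HW; ++i, ++o) s += xp[o] * yp[o];
      else    for (int i = 0; i < HW; ++i, ++o) s += xp[o];
      out(c, n) = s;
    }
  return out;
}

// y = x * m[c, n]
// [[Rcpp::export]]
NumericVector cpp_chan_scale_cn(NumericVector x, NumericMatrix m) {
  int HW, C, N; get_dims(x, HW, C, N);
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* xp = x.begin(); double* yp = y.begin();
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double v = m(c, n);
      for (int i = 0; i < HW; ++i, ++o) yp[o] = v * xp[o];
    }
  return y;
}

// broadcast a C x N matrix to a full (H, W, C, N) array
// [[Rcpp::export]]
NumericVector cpp_chan_expand_cn(NumericMatrix m, int H, int W) {
  const int C = m.nrow(), N = m.ncol(), HW = H * W;
  NumericVector y((size_t)HW * C * N);
  y.attr("dim") = IntegerVector::create(H, W, C, N);
  double* yp = y.begin();
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double v = m(c, n);
      for (int i = 0; i < HW; ++i, ++o) yp[o] = v;
    }
  return y;
}

// out = a[c] * g + b[c] + cc[c] * xhat   (batch-norm input gradient)
// [[Rcpp::export]]
NumericVector cpp_bn_bwd_combine(NumericVector g, NumericVector xhat,
                                 NumericVector a, NumericVector b,
                                 NumericVector cc) {
  int HW, C, N; get_dims(g, HW, C, N);
  NumericVector y(g.size());
  y.attr("dim") = g.attr("dim");
  const double* gp = g.begin(); const double* xp = xhat.begin();
  double* yp = y.begin();
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double ac = a[c], bc = b[c], ccc = cc[c];
      for (int i = 0; i < HW; ++i, ++o) yp[o] = ac * gp[o] + bc + ccc * xp[o];
    }
  return y;
}
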