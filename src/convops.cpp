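// Convolution and pooling kernels for the dual-stream network.
// Array layout follows R column-major conventions throughout:
//   activations  x[H, W, C, N]   (H fastest)
//   weights      w[kh, kw, Cin, Cout]
// "Same" padding with odd kernels keeps the spatial size; only the 2x2/stride-2
// max-pool changes it. The im2col buffer is (H*W) x (kh*kw*Cin): column
// r = ki + kh*(kj + kw*c) holds one shifted copy of the image, so writes are
// contiguous and a weight array can be viewed as a (kh*kw*Cin) x Cout matrix
// without copying.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static void im2col(const double* x, int H, int W, int C, int kh, int kw,
                   arma::mat& col) {
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  col.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kh * (kj + kw * c);
        double* dst = col.colptr(r);
        const int di = ki - ph, dj = kj - pw;
        const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
        const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
        for (int j = j0; j < j1; ++j) {
          const double* src = xc + (size_t)(j + dj) * H + di;
          double* d = dst + (size_t)j * H;
          for (int i = i0; i < i1; ++i) d[i] = src[i];
        }
      }
    }
  }
}

static void col2im_add(const arma::mat& col, int H, int W, int C, int kh, int kw,
                       double* x) {
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  for (int c = 0; c < C; ++c) {
    double* xc = x + (size_t)c * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kh * (kj + kw * c);
        const double* src0 = col.colptr(r);
        const int di = ki - ph, dj = kj - pw;
        const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
        const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
        for (int j = j0; j < j1; ++j) {
          double* d = xc + (size_t)(j + dj) * H + di;
          const double* src = src0 + (size_t)j * H;
          for (int i = i0; i < i1; ++i) d[i] += src[i];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cn_conv_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector dx = x.attr("dim"), dw = w.attr("dim");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int kh = dw[0], kw = dw[1], F = dw[3];
  if (dw[2] != C) stop("conv: weight Cin (%d) != input channels (%d)", dw[2], C);
  const int K = kh * kw * C, P = H * W;
  arma::mat wm(const_cast<double*>(w.begin()), K, F, false, true);
  NumericVector y((R_xlen_t)H * W * F * N);
  y.attr("dim") = IntegerVector::create(H, W, F, N);
  arma::mat col(P, K);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, col);
    arma::mat ym(y.begin() + (size_t)n * P * F, P, F, false, true);
    ym = col * wm;
    for (int f = 0; f < F; ++f) ym.col(f) += b[f];
  }
  return y;
}

// [[Rcpp::export]]
List cn_conv_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector dx_ = x.attr("dim"), dw_ = w.attr("dim");
  const int H = dx_[0], W = dx_[1], C = dx_[2], N = dx_[3];
  const int kh = dw_[0], kw = dw_[1], F = dw_[3];
  const int K = kh * kw * C, P = H * W;
  arma::mat wm(const_cast<double*>(w.begin()), K, F, false, true);
  NumericVector dxv((R_xlen_t)H * W * C * N);
  dxv.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector dwv((R_xlen_t)kh * kw * C * F);
  dwv.attr("dim") = IntegerVector::create(kh, kw, C, F);
  NumericVector dbv(F);
  arma::mat dwm(dwv.begin(), K, F, false, true);
  arma::vec dbm(dbv.begin(), F, false, true);
  arma::mat col(P, K);
  arma::mat dcol(P, K);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, col);
    arma::mat dym(const_cast<double*>(dy.begin()) + (size_t)n * P * F, P, F,
                  false, true);
    dwm += col.t() * dym;
    dbm += arma::sum(dym, 0).t();
    dcol = dym * wm.t();
    col2im_add(dcol, H, W, C, kh, kw, dxv.begin() + (size_t)n * H * W * C);
  }
  return List::create(_["dx"] = dxv, _["dw"] = dwv, _["db"] = dbv);
}

// [[Rcpp::export]]
List cn_pool_fwd(NumericVector x) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  if (H % 2 || W % 2) stop("pool: spatial size (%d x %d) not divisible by 2", H, W);
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx((R_xlen_t)Ho * Wo * C * N);  // 0-based linear index into x
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  for (R_xlen_t nc = 0; nc < (R_xlen_t)N * C; ++nc) {
    const size_t off = (size_t)nc * H * W;
    const size_t offo = (size_t)nc * Ho * Wo;
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        size_t best = off + (size_t)(2 * j) * H + 2 * i;
        double bv = xp[best];
        const size_t cand[3] = {best + 1, best + (size_t)H, best + (size_t)H + 1};
        for (int t = 0; t < 3; ++t)
          if (xp[cand[t]] > bv) { bv = xp[cand[t]]; best = cand[t]; }
        yp[offo + (size_t)j * Ho + i] = bv;
        ip[offo + (size_t)j * Ho + i] = (int)best;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cn_pool_bwd(IntegerVector idx, NumericVector dy, IntegerVector dims) {
  NumericVector dx((R_xlen_t)dims[0] * dims[1] * dims[2] * dims[3]);
  dx.attr("dim") = dims;
  const R_xlen_t n = dy.size();
  for (R_xlen_t t = 0; t < n; ++t) dx[idx[t]] += dy[t];
  return dx;
}
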