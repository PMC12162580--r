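#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Feature maps are 4-D R arrays with dim (H, W, N, C): spatial rows fastest,
// then columns, then batch, then channel.  im2col lowers a same-padded,
// stride-1 convolution to one BLAS gemm done on the R side.
//
// Column layout of the patch matrix: column index = ki + k*kj + k*k*c
// (kernel row offset fastest, then kernel column, then input channel),
// matching an R weight array of dim (k, k, Cin, Cout) flattened column-major.
// Row index = h + H*w + H*W*n.

static void im2col_fill(const double* xp, double* op, int H, int W, int N,
                        int C, int k);

// [[Rcpp::export(name = ".im2col_nn")]]
NumericMatrix im2col_nn(NumericVector x, int k) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("im2col: input must be a 4-D (H,W,N,C) array");
  const int H = d[0], W = d[1], N = d[2], C = d[3];
  NumericMatrix out((R_xlen_t)H * W * N, (R_xlen_t)k * k * C);
  im2col_fill(x.begin(), out.begin(), H, W, N, C, k);
  return out;
}

// Fills a caller-owned buffer (reused across calls to avoid repeated
// large allocations); buf must be a numeric matrix of exactly
// (H*W*N) x (k*k*C).
// [[Rcpp::export(name = ".im2col_into_nn")]]
NumericMatrix im2col_into_nn(NumericMatrix buf, NumericVector x, int k) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], N = d[2], C = d[3];
  if (buf.nrow() != (R_xlen_t)H * W * N || buf.ncol() != (R_xlen_t)k * k * C)
    stop("im2col buffer has wrong shape");
  im2col_fill(x.begin(), buf.begin(), H, W, N, C, k);
  return buf;
}

static void im2col_fill(const double* xp, double* op, int H, int W, int N,
                        int C, int k) {
  const int p = (k - 1) / 2;
  const R_xlen_t nrow = (R_xlen_t)H * W * N;
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        double* col = op + ((R_xlen_t)(ki + k * kj + k * k * c)) * nrow;
        for (int n = 0; n < N; ++n) {
          for (int w = 0; w < W; ++w) {
            const int xw = w + kj - p;
            double* dst = col + (R_xlen_t)H * (w + (R_xlen_t)W * n);
            if (xw < 0 || xw >= W) {
              std::memset(dst, 0, sizeof(double) * H);
              continue;
            }
            const double* src = xp + (R_xlen_t)H * (xw + (R_xlen_t)W * (n + (R_xlen_t)N * c));
            const int h0 = std::max(0, p - ki);             // first h with xh >= 0
            const int h1 = std::min(H, H + p - ki);         // one past last valid h
            if (h0 > 0) std::memset(dst, 0, sizeof(double) * h0);
            if (h1 < H) std::memset(dst + h1, 0, sizeof(double) * (H - h1));
            for (int h = h0; h < h1; ++h) dst[h] = src[h + ki - p];
          }
        }
      }
    }
  }
}

// Adjoint of im2col: scatter-add patch-matrix gradients back to input layout.
// [[Rcpp::export(name = ".col2im_nn")]]
NumericVector col2im_nn(NumericMatrix cols, int H, int W, int N, int C, int k) {
  const int p = (k - 1) / 2;
  const R_xlen_t nrow = (R_xlen_t)H * W * N;
  NumericVector dx((R_xlen_t)H * W * N * C);
  double* xp = dx.begin();
  const double* cp = cols.begin();
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const double* col = cp + ((R_xlen_t)(ki + k * kj + k * k * c)) * nrow;
        for (int n = 0; n < N; ++n) {
          for (int w = 0; w < W; ++w) {
            const int xw = w + kj - p;
            if (xw < 0 || xw >= W) continue;
            const double* src = col + (R_xlen_t)H * (w + (R_xlen_t)W * n);
            double* dst = xp + (R_xlen_t)H * (xw + (R_xlen_t)W * (n + (R_xlen_t)N * c));
            const int h0 = std::max(0, p - ki);
            const int h1 = std::min(H, H + p - ki);
            for (int h = h0; h < h1; ++h) dst[h + ki - p] += src[h];
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, N, C);
  return dx;
}

// 2x2 max pooling, stride 2.  Returns pooled map and 1-based linear argmax
// indices into the input (for the backward scatter).
// [[Rcpp::export(name = ".maxpool2_nn")]]
List maxpool2_nn(NumericVector x) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], N = d[2], C = d[3];
  if (H % 2 || W % 2) stop("maxpool: spatial side must be even");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out((R_xlen_t)Ho * Wo * N * C);
  IntegerVector idx((R_xlen_t)Ho * Wo * N * C);
  const double* xp = x.begin();
  R_xlen_t o = 0;
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          const R_xlen_t base = 2 * ho + (R_xlen_t)H * (2 * wo + (R_xlen_t)W * (n + (R_xlen_t)N * c));
          R_xlen_t best = base;
          double bv = xp[base];
          const R_xlen_t cand[3] = {base + 1, base + H, base + H + 1};
          for (int q = 0; q < 3; ++q)
            if (xp[cand[q]] > bv) { bv = xp[cand[q]]; best = cand[q]; }
          out[o] = bv;
          idx[o] = (int)(best + 1);
          ++o;
        }
  out.attr("dim") = IntegerVector::create(Ho, Wo, N, C);
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_bwd_nn")]]
NumericVector maxpool2_bwd_nn(NumericVector dout, IntegerVector idx,
                              IntegerVector xdim) {
  NumericVector dx((R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  const R_xlen_t n = dout.size();
  for (R_xlen_t i = 0; i < n; ++i) dx[idx[i] - 1] += dout[i];
  dx.attr("dim") = xdim;
  return dx;
}
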