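// Convolution engine: shift-and-GEMM over kernel offsets, stride 1,
// same-size zero padding. No im2col matrix is materialized; each kernel
// offset contributes one BLAS GEMM with a row-offset view into a padded
// copy of the input.
//
// INTERNAL tensor layout is channels-last: a 4-axis array with dims
// (batch N, height H, width W, channels C), column-major, so the linear
// offset of (n, h, w, c) is n + N*(h + H*(w + W*c)). Viewed as a matrix
// this is (N*H*W rows) x (C cols) with one column per channel.
//
// Weights for a k x k convolution C_in -> C_out are a (C_in*k*k) x C_out
// matrix; row index r = kw + k*kh + k*k*c addresses input channel c and
// kernel tap (kh, kw), kh/kw in [0, k). The operation is cross-correlation:
//   y(n, h, w, co) = b[co] + sum_{c,kh,kw} W[r, co] * x(n, h+kh-p, w+kw-p, c)
// with p = (k-1)/2 and out-of-range taps reading zero.
//
// For each offset (kh, kw) the contribution over the padded grid is
//   Ypad[j] += Xpad[j + delta] * Wslice,  delta = N*(dy + Hp*dx),
// which is exact for every valid (non-pad) output row; garbage lands only
// in pad rows of Ypad and is dropped on extraction. The same row-offset
// trick (with -delta) yields the input gradient, and transposed GEMMs give
// the weight gradient, so the whole backward pass is BLAS as well.

#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
using namespace Rcpp;

static void dims4(const NumericVector& x, int& N, int& H, int& W, int& C) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-axis (N, H, W, C) array");
  N = d[0]; H = d[1]; W = d[2]; C = d[3];
}

// copy (N,H,W,C) into zero-initialized (N,Hp,Wp,C) with spatial pad p
static void pad_into(const double* x, double* xp, int N, int H, int W, int C,
                     int p) {
  const int Hp = H + 2 * p, Wp = W + 2 * p;
  std::fill(xp, xp + (size_t)N * Hp * Wp * C, 0.0);
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < W; ++w) {
      const double* src = x + (size_t)N * (H * ((size_t)w + (size_t)W * c));
      double* dst = xp + (size_t)N * (p + (size_t)Hp * (w + p + (size_t)Wp * c));
      std::copy(src, src + (size_t)N * H, dst);
    }
}

// extract the valid region of (N,Hp,Wp,C) back into (N,H,W,C)
static void unpad_from(const double* xp, double* x, int N, int H, int W, int C,
                       int p) {
  const int Hp = H + 2 * p, Wp = W + 2 * p;
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < W; ++w) {
      const double* src = xp + (size_t)N * (p + (size_t)Hp * (w + p + (size_t)Wp * c));
      double* dst = x + (size_t)N * (H * ((size_t)w + (size_t)W * c));
      std::copy(src, src + (size_t)N * H, dst);
    }
}

// weight slice for offset (kh, kw): (C x Cout), rows strided by k*k
static void wslice(const double* W, int k, int C, int Cout, int kh, int kw,
                   std::vector<double>& buf) {
  const int R = C * k * k, base = kw + k * kh;
  buf.resize((size_t)C * Cout);
  for (int co = 0; co < Cout; ++co)
    for (int c = 0; c < C; ++c)
      buf[c + (size_t)C * co] = W[base + k * k * c + (size_t)R * co];
}

// [[Rcpp::export(name = ".conv_fwd_cpp")]]
NumericVector conv_fwd_cpp(NumericVector x, NumericMatrix Wt, NumericVector b,
                           int k) {
  int N, H, W, C;
  dims4(x, N, H, W, C);
  const int p = (k - 1) / 2;
  if (Wt.nrow() != C * k * k) stop("weight rows do not match C_in*k*k");
  const int Cout = Wt.ncol();
  const int Hp = H + 2 * p, Wp = W + 2 * p;
  const size_t rows = (size_t)N * Hp * Wp;
  const int irows = (int)rows;

  NumericVector out((R_xlen_t)N * H * W * Cout);
  out.attr("dim") = IntegerVector::create(N, H, W, Cout);

  if (p == 0) {
    // plain GEMM, no padding
    const double one = 1.0, zero = 0.0;
    const int m = N * H * W;
    // y = x * W
    F77_CALL(dgemm)("N", "N", &m, &Cout, &C, &one, x.begin(), &m,
                    Wt.begin(), &C, &zero, out.begin(), &m FCONE FCONE);
    for (int co = 0; co < Cout; ++co) {
      double* o = out.begin() + (size_t)m * co;
      const double bc = b[co];
      for (int i = 0; i < m; ++i) o[i] += bc;
    }
    return out;
  }

  std::vector<double> xp(rows * C), yp(rows * Cout), wbuf;
  pad_into(x.begin(), xp.data(), N, H, W, C, p);
  for (int co = 0; co < Cout; ++co)
    std::fill(yp.begin() + rows * co, yp.begin() + rows * (co + 1), b[co]);

  const double one = 1.0;
  for (int kh = 0; kh < k; ++kh)
    for (int kw = 0; kw < k; ++kw) {
      const int dy = kh - p, dx = kw - p;
      const long delta = (long)N * (dy + (long)Hp * dx);
      wslice(Wt.begin(), k, C, Cout, kh, kw, wbuf);
      const double* A = xp.data() + (delta > 0 ? delta : 0);
      double* Cm = yp.data() + (delta > 0 ? 0 : -delta);
      const int m = irows - (int)(delta > 0 ? delta : -delta);
      F77_CALL(dgemm)("N", "N", &m, &Cout, &C, &one, A, &irows,
                      wbuf.data(), &C, &one, Cm, &irows FCONE FCONE);
    }
  unpad_from(yp.data(), out.begin(), N, H, W, Cout, p);
  return out;
}

// [[Rcpp::export(name = ".conv_bwd_cpp")]]
List conv_bwd_cpp(NumericVector x, NumericMatrix Wt, NumericVector gy, int k) {
  int N, H, W, C;
  dims4(x, N, H, W, C);
  const int p = (k - 1) / 2;
  const int Cout = Wt.ncol();
  const int R = C * k * k;

  NumericVector gx((R_xlen_t)N * H * W * C);
  gx.attr("dim") = IntegerVector::create(N, H, W, C);
  NumericMatrix gW(R, Cout);
  NumericVector gb(Cout);

  const int m0 = N * H * W;
  for (int co = 0; co < Cout; ++co) {
    const double* g = gy.begin() + (size_t)m0 * co;
    double s = 0.0;
    for (int i = 0; i < m0; ++i) s += g[i];
    gb[co] = s;
  }

  const double one = 1.0, zero = 0.0;
  if (p == 0) {
    // gx = gy * W^T ; gW = x^T * gy
    F77_CALL(dgemm)("N", "T", &m0, &C, &Cout, &one, gy.begin(), &m0,
                    Wt.begin(), &C, &zero, gx.begin(), &m0 FCONE FCONE);
    F77_CALL(dgemm)("T", "N", &C, &Cout, &m0, &one, x.begin(), &m0,
                    gy.begin(), &m0, &zero, gW.begin(), &C FCONE FCONE);
    return List::create(Named("gx") = gx, Named("gW") = gW, Named("gb") = gb);
  }

  const int Hp = H + 2 * p, Wp = W + 2 * p;
  const size_t rows = (size_t)N * Hp * Wp;
  const int irows = (int)rows;
  std::vector<double> xp(rows * C), gyp(rows * Cout), gxp(rows * C, 0.0);
  std::vector<double> wbuf, gwbuf((size_t)C * Cout);
  pad_into(x.begin(), xp.data(), N, H, W, C, p);
  pad_into(gy.begin(), gyp.data(), N, H, W, Cout, p);

  for (int kh = 0; kh < k; ++kh)
    for (int kw = 0; kw < k; ++kw) {
      const int dy = kh - p, dx = kw - p;
      const long delta = (long)N * (dy + (long)Hp * dx);
      const long ad = delta > 0 ? delta : 0;   // offset into X-side
      const long bd = delta > 0 ? 0 : -delta;  // offset into Y-side
      const int m = irows - (int)(ad + bd);
      // gXpad[j + delta] += gYpad[j] * Wslice^T
      wslice(Wt.begin(), k, C, Cout, kh, kw, wbuf);
      F77_CALL(dgemm)("N", "T", &m, &C, &Cout, &one, gyp.data() + bd, &irows,
                      wbuf.data(), &C, &one, gxp.data() + ad, &irows FCONE FCONE);
      // gWslice = Xpad(+delta)^T * gYpad
      F77_CALL(dgemm)("T", "N", &C, &Cout, &m, &one, xp.data() + ad, &irows,
                      gyp.data() + bd, &irows, &zero, gwbuf.data(), &C FCONE FCONE);
      const int base = kw + k * kh;
      for (int co = 0; co < Cout; ++co)
        for (int c = 0; c < C; ++c)
          gW(base + k * k * c, co) = gwbuf[c + (size_t)C * co];
    }
  unpad_from(gxp.data(), gx.begin(), N, H, W, C, p);
  return List::create(Named("gx") = gx, Named("gW") = gW, Named("gb") = gb);
}

// PReLU with per-channel learnable slope; channels-last layout makes each
// channel a contiguous block.

// [[Rcpp::export(name = ".prelu_fwd_cpp")]]
NumericVector prelu_fwd_cpp(NumericVector x, NumericVector a) {
  int N, H, W, C;
  dims4(x, N, H, W, C);
  if (a.size() != C) stop("slope length must equal channel count");
  NumericVector y((R_xlen_t)x.size());
  y.attr("dim") = x.attr("dim");
  const size_t blk = (size_t)N * H * W;
  for (int c = 0; c < C; ++c) {
    const double ac = a[c];
    const double* xs = x.begin() + blk * c;
    double* ys = y.begin() + blk * c;
    for (size_t i = 0; i < blk; ++i)
      ys[i] = xs[i] > 0 ? xs[i] : ac * xs[i];
  }
  return y;
}

// [[Rcpp::export(name = ".prelu_bwd_cpp")]]
List prelu_bwd_cpp(NumericVector x, NumericVector a, NumericVector g) {
  int N, H, W, C;
  dims4(x, N, H, W, C);
  NumericVector gx((R_xlen_t)x.size());
  gx.attr("dim") = x.attr("dim");
  NumericVector ga(C);
  const size_t blk = (size_t)N * H * W;
  for (int c = 0; c < C; ++c) {
    const double ac = a[c];
    const double* xs = x.begin() + blk * c;
    const double* gs = g.begin() + blk * c;
    double* gxs = gx.begin() + blk * c;
    double acc = 0.0;
    for (size_t i = 0; i < blk; ++i) {
      if (xs[i] > 0) {
        gxs[i] = gs[i];
      } else {
        gxs[i] = ac * gs[i];
        acc += gs[i] * xs[i];
      }
    }
    ga[c] = acc;
  }
  return List::create(Named("gx") = gx, Named("ga") = ga);
}
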