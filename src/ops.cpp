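#include <Rcpp.h>
#include <R_ext/BLAS.h>
#include <cstring>
#include <vector>
using namespace Rcpp;

// Convolution kernels.  Tensors are column-major R arrays laid out
// channel-first, [C, H, W, N]: for a fixed pixel all channels are
// contiguous, so each kernel tap moves a C-length strip with memcpy.  A
// patch (im2col) matrix has one row per (c, ki, kj) tap (c fastest,
// matching the column-major flattening of a [C, k, k] weight block) and one
// column per (ho, wo, n) output position (ho fastest).  Patches are
// materialised in cache-sized column tiles and fed straight to BLAS dgemm,
// so the full patch matrix never exists in memory.

static const int TILE = 4096;   // patch-matrix columns per tile

static void dgemm(char ta, char tb, int m, int n, int kk,
                  const double* a, int lda, const double* b, int ldb,
                  double* c, int ldc, double alpha = 1.0, double beta = 0.0) {
  F77_CALL(dgemm)(&ta, &tb, &m, &n, &kk, &alpha, a, &lda, b, &ldb,
                  &beta, c, &ldc FCONE FCONE);
}

// fill patch columns j0..j1-1 into buf (column-major, k*k*C rows)
static void im2col_tile(const double* xp, int C, int H, int W,
                        int Ho, int Wo, int k, int stride, int pad,
                        long j0, long j1, double* buf) {
  long nrow = (long)k * k * C;
  for (long j = j0; j < j1; ++j) {
    long rem = j;
    int n = (int)(rem / ((long)Ho * Wo)); rem -= (long)n * Ho * Wo;
    int wo = (int)(rem / Ho);
    int ho = (int)(rem % Ho);
    double* dst = buf + (j - j0) * nrow;
    const double* xn = xp + (long)C * H * W * n;
    int h0 = ho * stride - pad;
    int w0 = wo * stride - pad;
    for (int kj = 0; kj < k; ++kj) {
      int w = w0 + kj;
      for (int ki = 0; ki < k; ++ki) {
        int h = h0 + ki;
        double* d = dst + (long)C * (ki + k * kj);
        if (h < 0 || h >= H || w < 0 || w >= W)
          std::memset(d, 0, sizeof(double) * C);
        else
          std::memcpy(d, xn + (long)C * (h + (long)H * w), sizeof(double) * C);
      }
    }
  }
}

// scatter-add patch columns j0..j1-1 of buf back into x (adjoint of
// im2col_tile); overlapping taps accumulate
static void col2im_tile(const double* buf, int C, int H, int W,
                        int Ho, int Wo, int k, int stride, int pad,
                        long j0, long j1, double* xp) {
  long nrow = (long)k * k * C;
  for (long j = j0; j < j1; ++j) {
    long rem = j;
    int n = (int)(rem / ((long)Ho * Wo)); rem -= (long)n * Ho * Wo;
    int wo = (int)(rem / Ho);
    int ho = (int)(rem % Ho);
    const double* src = buf + (j - j0) * nrow;
    double* xn = xp + (long)C * H * W * n;
    int h0 = ho * stride - pad;
    int w0 = wo * stride - pad;
    for (int kj = 0; kj < k; ++kj) {
      int w = w0 + kj;
      if (w < 0 || w >= W) continue;
      for (int ki = 0; ki < k; ++ki) {
        int h = h0 + ki;
        if (h < 0 || h >= H) continue;
        const double* s = src + (long)C * (ki + k * kj);
        double* d = xn + (long)C * (h + (long)H * w);
        for (int c = 0; c < C; ++c) d[c] += s[c];
      }
    }
  }
}

// y[Cout, Ho, Wo, N] = W' * patches(x) + b
// [[Rcpp::export]]
NumericVector conv_fwd_cpp(NumericVector x, NumericMatrix w, NumericVector b,
                           int C, int H, int W, int N,
                           int k, int stride, int pad) {
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  int cout = w.ncol();
  long nrow = (long)k * k * C, ncols = (long)Ho * Wo * N;
  std::vector<double> buf((long)TILE * nrow);
  NumericVector y(Rcpp::no_init((long)cout * ncols));
  for (long j0 = 0; j0 < ncols; j0 += TILE) {
    long j1 = std::min(ncols, j0 + TILE);
    im2col_tile(x.begin(), C, H, W, Ho, Wo, k, stride, pad, j0, j1, buf.data());
    dgemm('T', 'N', cout, (int)(j1 - j0), (int)nrow, w.begin(), (int)nrow,
          buf.data(), (int)nrow, y.begin() + j0 * cout, cout);
  }
  if (b.size() > 0) {
    double* yp = y.begin();
    for (long j = 0; j < ncols; ++j)
      for (int c = 0; c < cout; ++c) yp[j * cout + c] += b[c];
  }
  y.attr("dim") = IntegerVector::create(cout, Ho, Wo, N);
  return y;
}

// gradients of conv_fwd wrt input, weights and bias
// [[Rcpp::export]]
List conv_bwd_cpp(NumericVector dy, NumericVector x, NumericMatrix w,
                  int C, int H, int W, int N, int k, int stride, int pad) {
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  int cout = w.ncol();
  long nrow = (long)k * k * C, ncols = (long)Ho * Wo * N;
  std::vector<double> buf((long)TILE * nrow), dbuf((long)TILE * nrow);
  NumericMatrix dw((int)nrow, cout);              // zero-initialised
  NumericVector db(cout);
  NumericVector dx((long)C * H * W * N);          // zero-initialised
  for (long j0 = 0; j0 < ncols; j0 += TILE) {
    long j1 = std::min(ncols, j0 + TILE);
    int m = (int)(j1 - j0);
    im2col_tile(x.begin(), C, H, W, Ho, Wo, k, stride, pad, j0, j1, buf.data());
    // dw += patches * dy_tile'
    dgemm('N', 'T', (int)nrow, cout, m, buf.data(), (int)nrow,
          dy.begin() + j0 * cout, cout, dw.begin(), (int)nrow, 1.0, 1.0);
    // patch gradient for this tile, scattered back into dx
    dgemm('N', 'N', (int)nrow, m, cout, w.begin(), (int)nrow,
          dy.begin() + j0 * cout, cout, dbuf.data(), (int)nrow);
    col2im_tile(dbuf.data(), C, H, W, Ho, Wo, k, stride, pad, j0, j1, dx.begin());
  }
  for (long j = 0; j < ncols; ++j)
    for (int c = 0; c < cout; ++c) db[c] += dy[j * cout + c];
  dx.attr("dim") = IntegerVector::create(C, H, W, N);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Transposed convolution (stride 2, pad 1, kernel k: exact doubling).
// a is the adjoint convolution's weight, [k*k*Cout, Cin]: the forward here
// is the input-gradient of a stride-2 conv mapping [2H] -> [H], i.e. a
// tiled GEMM followed by the col2im scatter.
// [[Rcpp::export]]
NumericVector convt_fwd_cpp(NumericVector x, NumericMatrix a, NumericVector b,
                            int C, int H, int W, int N, int k, int stride, int pad) {
  int cout = a.nrow() / (k * k);
  long nrow = a.nrow(), ncols = (long)H * W * N;
  int Hy = stride * H, Wy = stride * W;
  std::vector<double> buf((long)TILE * nrow);
  NumericVector y((long)cout * Hy * Wy * N);      // zero-init: col2im accumulates
  for (long j0 = 0; j0 < ncols; j0 += TILE) {
    long j1 = std::min(ncols, j0 + TILE);
    dgemm('N', 'N', (int)nrow, (int)(j1 - j0), C, a.begin(), (int)nrow,
          x.begin() + j0 * C, C, buf.data(), (int)nrow);
    col2im_tile(buf.data(), cout, Hy, Wy, H, W, k, stride, pad, j0, j1, y.begin());
  }
  if (b.size() > 0) {
    double* yp = y.begin();
    long npix = (long)Hy * Wy * N;
    for (long j = 0; j < npix; ++j)
      for (int c = 0; c < cout; ++c) yp[j * cout + c] += b[c];
  }
  y.attr("dim") = IntegerVector::create(cout, Hy, Wy, N);
  return y;
}

// [[Rcpp::export]]
List convt_bwd_cpp(NumericVector dy, NumericVector x, NumericMatrix a,
                   int C, int H, int W, int N, int k, int stride, int pad) {
  int cout = a.nrow() / (k * k);
  long nrow = a.nrow(), ncols = (long)H * W * N;
  int Hy = stride * H, Wy = stride * W;
  std::vector<double> buf((long)TILE * nrow);
  NumericMatrix da((int)nrow, C);
  NumericVector db(cout);
  NumericVector dx(Rcpp::no_init((long)C * H * W * N));
  for (long j0 = 0; j0 < ncols; j0 += TILE) {
    long j1 = std::min(ncols, j0 + TILE);
    int m = (int)(j1 - j0);
    im2col_tile(dy.begin(), cout, Hy, Wy, H, W, k, stride, pad, j0, j1, buf.data());
    dgemm('N', 'T', (int)nrow, C, m, buf.data(), (int)nrow,
          x.begin() + j0 * C, C, da.begin(), (int)nrow, 1.0, 1.0);
    dgemm('T', 'N', C, m, (int)nrow, a.begin(), (int)nrow,
          buf.data(), (int)nrow, dx.begin() + j0 * C, C);
  }
  long npix = (long)Hy * Wy * N;
  for (long j = 0; j < npix; ++j)
    for (int c = 0; c < cout; ++c) db[c] += dy[j * cout + c];
  dx.attr("dim") = IntegerVector::create(C, H, W, N);
  return List::create(_["dx"] = dx, _["da"] = da, _["db"] = db);
}

// ---- single-pass elementwise / per-channel kernels ------------------------

// [[Rcpp::export]]
NumericVector relu_fwd_cpp(NumericVector x) {
  NumericVector y(Rcpp::no_init(x.size()));
  for (long i = 0; i < (long)x.size(); ++i) y[i] = x[i] > 0 ? x[i] : 0.0;
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export]]
NumericVector relu_bwd_cpp(NumericVector dy, NumericVector y) {
  NumericVector dx(Rcpp::no_init(dy.size()));
  for (long i = 0; i < (long)dy.size(); ++i) dx[i] = y[i] > 0 ? dy[i] : 0.0;
  dx.attr("dim") = dy.attr("dim");
  return dx;
}

// [[Rcpp::export]]
NumericVector sigmoid_fwd_cpp(NumericVector x) {
  NumericVector y(Rcpp::no_init(x.size()));
  for (long i = 0; i < (long)x.size(); ++i) y[i] = 1.0 / (1.0 + std::exp(-x[i]));
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export]]
NumericVector sigmoid_bwd_cpp(NumericVector dy, NumericVector y) {
  NumericVector dx(Rcpp::no_init(dy.size()));
  for (long i = 0; i < (long)dy.size(); ++i) dx[i] = dy[i] * y[i] * (1.0 - y[i]);
  dx.attr("dim") = dy.attr("dim");
  return dx;
}

// per-channel mean and variance of a [C, ...] tensor (population variance)
// [[Rcpp::export]]
List channel_stats_cpp(NumericVector x, int C) {
  long m = x.size() / C;
  NumericVector mu(C), v(C);
  const double* xp = x.begin();
  for (long j = 0; j < m; ++j)
    for (int c = 0; c < C; ++c) mu[c] += xp[j * C + c];
  for (int c = 0; c < C; ++c) mu[c] /= m;
  for (long j = 0; j < m; ++j)
    for (int c = 0; c < C; ++c) {
      double d = xp[j * C + c] - mu[c];
      v[c] += d * d;
    }
  for (int c = 0; c < C; ++c) v[c] /= m;
  return List::create(_["mean"] = mu, _["var"] = v);
}

// y[c, j] = x[c, j] * scale[c] + shift[c]
// [[Rcpp::export]]
NumericVector channel_affine_cpp(NumericVector x, NumericVector scale,
                                 NumericVector shift) {
  int C = scale.size();
  long m = x.size() / C;
  NumericVector y(Rcpp::no_init(x.size()));
  const double* xp = x.begin(); double* yp = y.begin();
  for (long j = 0; j < m; ++j)
    for (int c = 0; c < C; ++c) yp[j * C + c] = xp[j * C + c] * scale[c] + shift[c];
  y.attr("dim") = x.attr("dim");
  return y;
}

// per-channel sums of dy and dy * xhat in one pass
// [[Rcpp::export]]
List channel_dots_cpp(NumericVector dy, NumericVector xhat, int C) {
  long m = dy.size() / C;
  NumericVector s(C), sx(C);
  const double* dp = dy.begin(); const double* hp = xhat.begin();
  for (long j = 0; j < m; ++j)
    for (int c = 0; c < C; ++c) {
      s[c] += dp[j * C + c];
      sx[c] += dp[j * C + c] * hp[j * C + c];
    }
  return List::create(_["sum"] = s, _["dot"] = sx);
}

// training-mode BN input gradient:
// dx[c,j] = (dy[c,j]*gamma[c] - a[c] - xhat[c,j]*b[c]) * inv[c]
// [[Rcpp::export]]
NumericVector bn_bwd_cpp(NumericVector dy, NumericVector xhat,
                         NumericVector gamma, NumericVector a,
                         NumericVector b, NumericVector inv) {
  int C = gamma.size();
  long m = dy.size() / C;
  NumericVector dx(Rcpp::no_init(dy.size()));
  const double* dp = dy.begin(); const double* hp = xhat.begin();
  double* xp = dx.begin();
  for (long j = 0; j < m; ++j)
    for (int c = 0; c < C; ++c)
      xp[j * C + c] = (dp[j * C + c] * gamma[c] - a[c] - hp[j * C + c] * b[c]) * inv[c];
  dx.attr("dim") = dy.attr("dim");
  return dx;
}

// x[c, hw, n] scaled per (c, n): y[c, hw, n] = x[c, hw, n] * w[c, n]
// [[Rcpp::export]]
NumericVector scale_channels_cpp(NumericVector x, NumericMatrix w, int HW) {
  int C = w.nrow(), N = w.ncol();
  NumericVector y(Rcpp::no_init(x.size()));
  const double* xp = x.begin(); double* yp = y.begin();
  for (int n = 0; n < N; ++n)
    for (long j = 0; j < HW; ++j)
      for (int c = 0; c < C; ++c) {
        long i = (long)C * HW * n + j * C + c;
        yp[i] = xp[i] * w[n * C + c];
      }
  y.attr("dim") = x.attr("dim");
  return y;
}

// gradients of scale_channels: dx = dy * w (broadcast), dw[c,n] = sum_j dy*x
// [[Rcpp::export]]
List scale_channels_bwd_cpp(NumericVector dy, NumericVector x,
                            NumericMatrix w, int HW) {
  int C = w.nrow(), N = w.ncol();
  NumericVector dx(Rcpp::no_init(dy.size()));
  NumericMatrix dw(C, N);
  const double* dp = dy.begin(); const double* xp = x.begin();
  double* ddx = dx.begin();
  for (int n = 0; n < N; ++n)
    for (long j = 0; j < HW; ++j)
      for (int c = 0; c < C; ++c) {
        long i = (long)C * HW * n + j * C + c;
        ddx[i] = dp[i] * w[n * C + c];
        dw[n * C + c] += dp[i] * xp[i];
      }
  dx.attr("dim") = dy.attr("dim");
  return List::create(_["dx"] = dx, _["dw"] = dw);
}
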