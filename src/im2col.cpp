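#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
# define FCONE
#endif
using namespace Rcpp;

// im2col gather into a raw buffer. idx is n x k2, 1-based cell indices
// with n+1 marking out-of-bounds (zero) sources.
static void gather_cols(const double* xp, const int* ip, int n, int C,
                        int k2, double* cols) {
  for (int k = 0; k < k2; ++k) {
    const int* ic = ip + (size_t)k * n;
    for (int c = 0; c < C; ++c) {
      const double* xc = xp + (size_t)c * n;
      double* out = cols + ((size_t)k * C + c) * n;
      for (int p = 0; p < n; ++p) {
        const int s = ic[p] - 1;
        out[p] = (s < n) ? xc[s] : 0.0;
      }
    }
  }
}

// Same-padding k x k convolution: Y = im2col(X) %*% W + b.
// X: n x C (cells in column-major canvas order), W: (k2*C) x F, b: F.
// Temporaries live on the C++ heap, outside R's garbage collector.
// [[Rcpp::export]]
NumericMatrix conv_fwd_cpp(const NumericMatrix& X, const IntegerMatrix& idx,
                           const NumericMatrix& W, const NumericVector& b) {
  const int n = X.nrow(), C = X.ncol(), k2 = idx.ncol(), F = W.ncol();
  const int K = k2 * C;
  std::vector<double> cols((size_t)n * K);
  gather_cols(REAL(X), INTEGER(idx), n, C, k2, cols.data());
  NumericMatrix Y(n, F);
  const double one = 1.0, zero = 0.0;
  F77_CALL(dgemm)("N", "N", &n, &F, &K, &one, cols.data(), &n,
                  REAL(W), &K, &zero, REAL(Y), &n FCONE FCONE);
  double* yp = REAL(Y);
  for (int f = 0; f < F; ++f) {
    const double bf = b[f];
    double* yc = yp + (size_t)f * n;
    for (int p = 0; p < n; ++p) yc[p] += bf;
  }
  return Y;
}

// Backward pass of conv_fwd_cpp. Recomputes the im2col buffer from the
// saved layer input X; returns dX, dW, db.
// [[Rcpp::export]]
List conv_bwd_cpp(const NumericMatrix& dY, const NumericMatrix& X,
                  const IntegerMatrix& idx, const NumericMatrix& W) {
  const int n = X.nrow(), C = X.ncol(), k2 = idx.ncol(), F = W.ncol();
  const int K = k2 * C;
  std::vector<double> cols((size_t)n * K);
  gather_cols(REAL(X), INTEGER(idx), n, C, k2, cols.data());
  const double one = 1.0, zero = 0.0;
  NumericMatrix dW(K, F);
  F77_CALL(dgemm)("T", "N", &K, &F, &n, &one, cols.data(), &n,
                  REAL(dY), &n, &zero, REAL(dW), &K FCONE FCONE);
  NumericVector db(F);
  const double* dyp = REAL(dY);
  for (int f = 0; f < F; ++f) {
    double s = 0.0;
    const double* dc = dyp + (size_t)f * n;
    for (int p = 0; p < n; ++p) s += dc[p];
    db[f] = s;
  }
  std::vector<double> dcols((size_t)n * K);
  F77_CALL(dgemm)("N", "T", &n, &K, &F, &one, REAL(dY), &n,
                  REAL(W), &K, &zero, dcols.data(), &n FCONE FCONE);
  NumericMatrix dX(n, C);
  double* dxp = REAL(dX);
  const int* ip = INTEGER(idx);
  for (int k = 0; k < k2; ++k) {
    const int* ic = ip + (size_t)k * n;
    for (int c = 0; c < C; ++c) {
      const double* dc = dcols.data() + ((size_t)k * C + c) * n;
      double* out = dxp + (size_t)c * n;
      for (int p = 0; p < n; ++p) {
        const int s = ic[p] - 1;
        if (s < n) out[s] += dc[p];
      }
    }
  }
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// ELU and its derivative (alpha = 1), applied elementwise.
// [[Rcpp::export]]
NumericMatrix elu_cpp(const NumericMatrix& X) {
  NumericMatrix Y(X.nrow(), X.ncol());
  const double* xp = REAL(X);
  double* yp = REAL(Y);
  const size_t m = (size_t)X.nrow() * X.ncol();
  for (size_t i = 0; i < m; ++i)
    yp[i] = (xp[i] > 0) ? xp[i] : std::expm1(xp[i]);
  return Y;
}

// [[Rcpp::export]]
NumericMatrix elu_grad_cpp(const NumericMatrix& X) {
  NumericMatrix Y(X.nrow(), X.ncol());
  const double* xp = REAL(X);
  double* yp = REAL(Y);
  const size_t m = (size_t)X.nrow() * X.ncol();
  for (size_t i = 0; i < m; ++i)
    yp[i] = (xp[i] > 0) ? 1.0 : std::exp(xp[i]);
  return Y;
}
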