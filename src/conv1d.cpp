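// Valid stride-1 1D convolution over a batch of multichannel signals.
//
// The batch (C, T, N) is laid flat as one long (C, T*N) signal; each kernel
// tap j contributes one dgemm against the contiguous column block starting
// at offset j, with no buffer ever copied (im2col-free). Outputs whose
// window straddles a sample boundary are masked afterwards: the forward
// pass gathers only within-sample columns, and the backward pass scatters
// the incoming gradient onto the flat grid with zeros at the straddling
// positions, which keeps every tap product exact.
#include <Rcpp.h>
#include <R_ext/BLAS.h>

using Rcpp::NumericMatrix;
using Rcpp::NumericVector;

static void dgemm(const char* ta, const char* tb, int m, int n, int k,
                  double alpha, const double* a, int lda, const double* b,
                  int ldb, double beta, double* c, int ldc) {
  F77_CALL(dgemm)(ta, tb, &m, &n, &k, &alpha, a, &lda, b, &ldb, &beta, c,
                  &ldc FCONE FCONE);
}

// [[Rcpp::export(name = ".conv1d_fwd_cpp")]]
NumericMatrix conv1d_fwd_cpp(const NumericMatrix& A, const NumericMatrix& W,
                             const NumericVector& b, int Tn, int N, int k) {
  const int C = A.nrow(), Cout = W.nrow();
  const int To = Tn - k + 1;
  const R_xlen_t L = (R_xlen_t)Tn * N - k + 1;
  std::vector<double> Zf((size_t)Cout * L, 0.0);
  for (int j = 0; j < k; ++j) {
    dgemm("N", "N", Cout, (int)L, C, 1.0, &W(0, j * C), Cout,
          &A(0, j), C, 1.0, Zf.data(), Cout);
  }
  NumericMatrix Z(Cout, To * N);
  for (int n = 0; n < N; ++n) {
    const double* src = Zf.data() + (size_t)n * Tn * Cout;
    double* dst = &Z(0, (R_xlen_t)n * To);
    std::memcpy(dst, src, sizeof(double) * (size_t)To * Cout);
  }
  for (R_xlen_t c = 0; c < (R_xlen_t)To * N; ++c) {
    for (int i = 0; i < Cout; ++i) Z(i, c) += b[i];
  }
  return Z;
}

// [[Rcpp::export(name = ".conv1d_bwd_cpp")]]
Rcpp::List conv1d_bwd_cpp(const NumericMatrix& A, const NumericMatrix& W,
                          const NumericMatrix& dZ, int Tn, int N, int k,
                          bool need_dX, bool need_dW) {
  const int C = A.nrow(), Cout = W.nrow();
  const int To = Tn - k + 1;
  const R_xlen_t L = (R_xlen_t)Tn * N - k + 1;
  // scatter dZ onto the flat grid (zeros where windows straddle samples)
  std::vector<double> dZf((size_t)Cout * L, 0.0);
  for (int n = 0; n < N; ++n) {
    const double* src = &dZ(0, (R_xlen_t)n * To);
    double* dst = dZf.data() + (size_t)n * Tn * Cout;
    std::memcpy(dst, src, sizeof(double) * (size_t)To * Cout);
  }
  Rcpp::List out;
  if (need_dW) {
    NumericMatrix dW(Cout, C * k);
    for (int j = 0; j < k; ++j) {
      dgemm("N", "T", Cout, C, (int)L, 1.0, dZf.data(), Cout,
            &A(0, j), C, 0.0, &dW(0, j * C), Cout);
    }
    NumericVector db(Cout);
    for (R_xlen_t c = 0; c < (R_xlen_t)To * N; ++c) {
      for (int i = 0; i < Cout; ++i) db[i] += dZ(i, c);
    }
    out["dW"] = dW;
    out["db"] = db;
  }
  if (need_dX) {
    NumericMatrix dX(C, (R_xlen_t)Tn * N);
    for (int j = 0; j < k; ++j) {
      dgemm("T", "N", C, (int)L, Cout, 1.0, &W(0, j * C), Cout,
            dZf.data(), Cout, 1.0, &dX(0, j), C);
    }
    out["dX"] = dX;
  }
  return out;
}
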