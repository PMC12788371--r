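#include <Rcpp.h>
using namespace Rcpp;

// im2col gather for channel-fastest feature matrices.
//
// X:   (in_len x N) input features, column-major
// idx: (K x P) 1-based indices into a feature column; 0 marks a padding
//      cell (reads as 0.0)
// out: (K, P*N) patch matrix, element (k, p + n*P)

// [[Rcpp::export]]
NumericMatrix cpp_im2col(const NumericMatrix& X, const IntegerMatrix& idx) {
  const int K = idx.nrow(), P = idx.ncol(), N = X.ncol(), L = X.nrow();
  NumericMatrix out(K, P * N);
  const double* x = X.begin();
  const int* id = idx.begin();
  double* o = out.begin();
  for (int n = 0; n < N; ++n) {
    const double* col = x + (size_t)n * L;
    double* blk = o + (size_t)n * (size_t)K * P;
    for (int p = 0; p < P; ++p) {
      const int* idc = id + (size_t)p * K;
      double* dest = blk + (size_t)p * K;
      for (int k = 0; k < K; ++k) {
        const int j = idc[k];
        dest[k] = (j > 0) ? col[j - 1] : 0.0;
      }
    }
  }
  return out;
}

// col2im scatter-add (transpose of cpp_im2col): accumulates patch
// gradients back onto the (in_len x N) input gradient.

// [[Rcpp::export]]
NumericMatrix cpp_col2im(const NumericMatrix& dM, const IntegerMatrix& idx,
                         const int in_len, const int N) {
  const int K = idx.nrow(), P = idx.ncol();
  NumericMatrix out(in_len, N);
  const double* dm = dM.begin();
  const int* id = idx.begin();
  double* o = out.begin();
  for (int n = 0; n < N; ++n) {
    double* col = o + (size_t)n * in_len;
    const double* blk = dm + (size_t)n * (size_t)K * P;
    for (int p = 0; p < P; ++p) {
      const int* idc = id + (size_t)p * K;
      const double* src = blk + (size_t)p * K;
      for (int k = 0; k < K; ++k) {
        const int j = idc[k];
        if (j > 0) col[j - 1] += src[k];
      }
    }
  }
  return out;
}
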