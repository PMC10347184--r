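#include <Rcpp.h>
using namespace Rcpp;

// im2col for batched 1-D convolution. Input xp is the (Lp*n) x C engine
// tensor (row index = (i-1)*Lp + t, time fastest within sample). Output is
// the (Lout*n) x (k*C) patch matrix with column index (j-1)*C + c, ready
// for a single GEMM against the (k*C) x F weight matrix.
// [[Rcpp::export]]
NumericMatrix cpp_im2col(const NumericMatrix& xp, int n, int Lp, int k,
                         int stride, int Lout) {
  const int C = xp.ncol();
  NumericMatrix out(Lout * n, k * C);
  const double* src = xp.begin();
  double* dst = out.begin();
  for (int j = 0; j < k; ++j) {
    for (int c = 0; c < C; ++c) {
      const double* scol = src + (R_xlen_t)c * Lp * n;
      double* dcol = dst + (R_xlen_t)(j * C + c) * Lout * n;
      for (int i = 0; i < n; ++i) {
        const double* s = scol + (R_xlen_t)i * Lp + j;
        double* d = dcol + (R_xlen_t)i * Lout;
        for (int o = 0; o < Lout; ++o) d[o] = s[(R_xlen_t)o * stride];
      }
    }
  }
  return out;
}

// Adjoint of one kernel-offset slice of cpp_im2col: scatter-adds the
// (Lout*n) x C gradient block for offset j (1-based) onto the padded input
// grid, modifying dxp in place (dxp is engine-private scratch).
// [[Rcpp::export]]
NumericMatrix cpp_col2im_offset(NumericMatrix dxp, const NumericMatrix& dXj,
                                int n, int Lp, int j, int stride, int Lout) {
  const int C = dXj.ncol();
  const double* src = dXj.begin();
  double* dst = dxp.begin();
  for (int c = 0; c < C; ++c) {
    const double* scol = src + (R_xlen_t)c * Lout * n;
    double* dcol = dst + (R_xlen_t)c * Lp * n;
    for (int i = 0; i < n; ++i) {
      const double* s = scol + (R_xlen_t)i * Lout;
      double* d = dcol + (R_xlen_t)i * Lp + (j - 1);
      for (int o = 0; o < Lout; ++o) d[(R_xlen_t)o * stride] += s[o];
    }
  }
  return dxp;
}
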