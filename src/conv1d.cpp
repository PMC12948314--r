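// Hot loops of the 1-D convolution layers: patch-matrix gather (im2col)
// and its transpose scatter (col2im).  Matrix products stay in R/BLAS.
#include <Rcpp.h>
using namespace Rcpp;

// Xp: padded input, dim (B, Lp, Cin).  I2: Lout x k matrix of 1-based
// input positions.  Returns the patch matrix (B*Lout, k*Cin).
// [[Rcpp::export(name = ".im2colC")]]
NumericMatrix im2colC(NumericVector Xp, IntegerVector dims,
                      IntegerMatrix I2) {
  const int B = dims[0], Lp = dims[1], Cin = dims[2];
  const int Lout = I2.nrow(), k = I2.ncol();
  NumericMatrix out(B * Lout, k * Cin);
  const double *x = Xp.begin();
  double *o = out.begin();
  for (int cin = 0; cin < Cin; ++cin) {
    const double *xc = x + (R_xlen_t)cin * B * Lp;
    for (int kk = 0; kk < k; ++kk) {
      double *col = o + ((R_xlen_t)(cin * k + kk)) * B * Lout;
      for (int t = 0; t < Lout; ++t) {
        const double *src = xc + (R_xlen_t)(I2(t, kk) - 1) * B;
        double *dst = col + (R_xlen_t)t * B;
        std::copy(src, src + B, dst);
      }
    }
  }
  return out;
}

// dXc: (B*Lout, k*Cin) patch-gradient matrix.  Accumulates into the
// padded input gradient, returned with dim (B, Lp, Cin).
// [[Rcpp::export(name = ".col2imC")]]
NumericVector col2imC(NumericMatrix dXc, IntegerVector dims,
                      IntegerMatrix I2) {
  const int B = dims[0], Lp = dims[1], Cin = dims[2];
  const int Lout = I2.nrow(), k = I2.ncol();
  NumericVector out((R_xlen_t)B * Lp * Cin);
  const double *g = dXc.begin();
  double *o = out.begin();
  for (int cin = 0; cin < Cin; ++cin) {
    double *oc = o + (R_xlen_t)cin * B * Lp;
    for (int kk = 0; kk < k; ++kk) {
      const double *col = g + ((R_xlen_t)(cin * k + kk)) * B * Lout;
      for (int t = 0; t < Lout; ++t) {
        double *dst = oc + (R_xlen_t)(I2(t, kk) - 1) * B;
        const double *src = col + (R_xlen_t)t * B;
        for (int b = 0; b < B; ++b) dst[b] += src[b];
      }
    }
  }
  out.attr("dim") = IntegerVector::create(B, Lp, Cin);
  return out;
}
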