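// Bilinear gather/scatter kernels for direction-field rectification.
// The stencil (4 corner indices + weights per pixel) is precomputed in R;
// these kernels apply it and its adjoint to multi-channel feature maps.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix cpp_bilinear_gather(const NumericMatrix& F,
                                  const IntegerMatrix& idx,
                                  const NumericMatrix& w) {
  const int n = F.nrow(), C = F.ncol();
  NumericMatrix out(n, C);
  for (int c = 0; c < C; ++c) {
    const double* fc = &F(0, c);
    double* oc = &out(0, c);
    for (int i = 0; i < n; ++i) {
      oc[i] = w(i, 0) * fc[idx(i, 0)] + w(i, 1) * fc[idx(i, 1)] +
              w(i, 2) * fc[idx(i, 2)] + w(i, 3) * fc[idx(i, 3)];
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_bilinear_scatter(const NumericMatrix& dF,
                                   const IntegerMatrix& idx,
                                   const NumericMatrix& w) {
  const int n = dF.nrow(), C = dF.ncol();
  NumericMatrix out(n, C);
  for (int c = 0; c < C; ++c) {
    const double* gc = &dF(0, c);
    double* oc = &out(0, c);
    for (int i = 0; i < n; ++i) {
      const double g = gc[i];
      oc[idx(i, 0)] += w(i, 0) * g;
      oc[idx(i, 1)] += w(i, 1) * g;
      oc[idx(i, 2)] += w(i, 2) * g;
      oc[idx(i, 3)] += w(i, 3) * g;
    }
  }
  return out;
}
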