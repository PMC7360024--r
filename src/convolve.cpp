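// Separable kernel correlation with replicate (edge-clamp) boundary.
// Hot path of the Gaussian pre-filter: called once per frame on full
// frames during animal detection and on small ROI crops during tracking.
// Column-pointer arithmetic keeps both passes contiguous and vectorizable.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix convolve_separable_cpp(NumericMatrix m, NumericVector k) {
  const int nr = m.nrow(), nc = m.ncol(), kl = k.size();
  const int r = (kl - 1) / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  const double* kp = k.begin();

  // vertical pass: each output column is a sum of shifted copies of the
  // input column, rows clamped to [0, nr-1]
  for (int j = 0; j < nc; ++j) {
    const double* src = &m[(size_t)j * nr];
    double* dst = &tmp[(size_t)j * nr];
    for (int i = 0; i < nr; ++i) dst[i] = 0.0;
    for (int t = 0; t < kl; ++t) {
      const double w = kp[t];
      const int off = t - r;
      int lo = std::max(0, -off), hi = std::min(nr, nr - off);
      for (int i = lo; i < hi; ++i) dst[i] += w * src[i + off];
      for (int i = 0; i < lo; ++i) dst[i] += w * src[0];
      for (int i = hi; i < nr; ++i) dst[i] += w * src[nr - 1];
    }
  }
  // horizontal pass: each output column accumulates whole neighbor columns
  for (int j = 0; j < nc; ++j) {
    double* dst = &out[(size_t)j * nr];
    for (int i = 0; i < nr; ++i) dst[i] = 0.0;
    for (int t = 0; t < kl; ++t) {
      int jj = j + t - r;
      if (jj < 0) jj = 0; else if (jj >= nc) jj = nc - 1;
      const double w = kp[t];
      const double* src = &tmp[(size_t)jj * nr];
      for (int i = 0; i < nr; ++i) dst[i] += w * src[i];
    }
  }
  return out;
}
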