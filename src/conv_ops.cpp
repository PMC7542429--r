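#include <Rcpp.h>
using namespace Rcpp;

// Hot loops of the convolution engine. Layout contract (see R/nn.R):
// samples are columns; each sample is a channel-first (C, H, W) tensor
// flattened column-major; `idx` is the per-sample im2col index matrix
// (ckk x P) flattened column-major, 1-based into the *unpadded* sample
// vector, with 0 marking zero-padding positions.

// gather: cols (ckk x P*N) from input x (CHW x N); idx == 0 reads 0.0
// [[Rcpp::export]]
NumericMatrix gather_cols(const NumericMatrix& x, const IntegerVector& idx,
                          int ckk) {
  const int L = idx.size();      // ckk * P
  const int P = L / ckk;
  const int n = x.ncol();
  NumericMatrix out(ckk, (R_xlen_t)P * n);
  for (int j = 0; j < n; ++j) {
    const double* xcol = &x(0, j);
    for (int p = 0; p < P; ++p) {
      double* ocol = &out(0, (R_xlen_t)j * P + p);
      const int* id = &idx[(R_xlen_t)p * ckk];
      for (int k = 0; k < ckk; ++k) ocol[k] = id[k] ? xcol[id[k] - 1] : 0.0;
    }
  }
  return out;
}

// scatter-add: dx (CHW x N) accumulated from dcols (ckk x P*N);
// idx == 0 (padding) is dropped
// [[Rcpp::export]]
NumericMatrix scatter_cols(const NumericMatrix& dcols,
                           const IntegerVector& idx, int chw) {
  const int ckk = dcols.nrow();
  const int L = idx.size();
  const int P = L / ckk;
  const int n = dcols.ncol() / P;
  NumericMatrix out(chw, n);
  for (int j = 0; j < n; ++j) {
    double* ocol = &out(0, j);
    for (int p = 0; p < P; ++p) {
      const double* dcol = &dcols(0, (R_xlen_t)j * P + p);
      const int* id = &idx[(R_xlen_t)p * ckk];
      for (int k = 0; k < ckk; ++k)
        if (id[k]) ocol[id[k] - 1] += dcol[k];
    }
  }
  return out;
}
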