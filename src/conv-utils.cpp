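#include <Rcpp.h>
using namespace Rcpp;

// im2col gather: stack k row-gathers of Ap (rows = taps[[u]]) side by side,
// giving the (L_out * B) x (k * C) column matrix of a 1D convolution.
// [[Rcpp::export(name = ".im2col_gather")]]
NumericMatrix im2col_gather(NumericMatrix Ap, List taps) {
  const int k = taps.size();
  const int C = Ap.ncol();
  IntegerVector t0 = taps[0];
  const int nr = t0.size();
  NumericMatrix out(nr, k * C);
  const int apn = Ap.nrow();
  for (int u = 0; u < k; ++u) {
    IntegerVector rows = taps[u];
    for (int c = 0; c < C; ++c) {
      const double* src = &Ap(0, c);
      double* dst = &out(0, u * C + c);
      for (int i = 0; i < nr; ++i) {
        const int r = rows[i] - 1;
        dst[i] = (r >= 0 && r < apn) ? src[r] : 0.0;
      }
    }
  }
  return out;
}

// col2im scatter-add: accumulate the k column blocks of dXcol back onto the
// padded activation rows (the adjoint of im2col_gather).
// [[Rcpp::export(name = ".col2im_scatter")]]
NumericMatrix col2im_scatter(NumericMatrix dXcol, List taps, int n_rows,
                             int C) {
  const int k = taps.size();
  NumericMatrix out(n_rows, C);
  IntegerVector t0 = taps[0];
  const int nr = t0.size();
  for (int u = 0; u < k; ++u) {
    IntegerVector rows = taps[u];
    for (int c = 0; c < C; ++c) {
      const double* src = &dXcol(0, u * C + c);
      double* dst = &out(0, c);
      for (int i = 0; i < nr; ++i) dst[rows[i] - 1] += src[i];
    }
  }
  return out;
}
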