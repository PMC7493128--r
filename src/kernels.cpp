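#include <Rcpp.h>
using namespace Rcpp;

// Sum over samples of sign(sin(phi_i - phi_j)) for every channel pair.
// X = cos(phases), Y = sin(phases), both C x K (column-major: one column
// per sample). Returns the C x C signed count; the phase lag index is
// |count| / K.
// [[Rcpp::export]]
NumericMatrix pli_sign_accum(NumericMatrix X, NumericMatrix Y) {
  const int C = X.nrow(), K = X.ncol();
  NumericMatrix acc(C, C);
  double *a = acc.begin();
  const double *px = X.begin(), *py = Y.begin();
  for (int t = 0; t < K; ++t) {
    const double *xt = px + (size_t)t * C;
    const double *yt = py + (size_t)t * C;
    for (int i = 0; i < C; ++i) {
      const double xi = xt[i], yi = yt[i];
      double *ai = a + (size_t)i * C; // column i, rows j > i
      for (int j = i + 1; j < C; ++j) {
        // sin(phi_i - phi_j) = yi*xj - xi*yj
        const double s = yi * xt[j] - xi * yt[j];
        ai[j] += (s > 0) - (s < 0);
      }
    }
  }
  // mirror the lower triangle (stored in column i, row j) to (i, j)
  for (int i = 0; i < C; ++i)
    for (int j = i + 1; j < C; ++j) acc(i, j) = acc(j, i);
  return acc;
}
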