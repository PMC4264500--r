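#include <Rcpp.h>
using namespace Rcpp;

// Causal IIR filtering of every column of X with transfer function
// b(z)/a(z), direct form II transposed, zero initial state.
// [[Rcpp::export]]
NumericMatrix iir_filter_mat(NumericVector b, NumericVector a,
                             NumericMatrix X) {
  const int nb = b.size(), na = a.size();
  const int n = X.nrow(), m = X.ncol();
  const double a0 = a[0];
  if (a0 == 0.0) stop("a[0] must be non-zero");
  const int nz = std::max(na, nb) - 1;
  std::vector<double> bn(nz + 1, 0.0), an(nz + 1, 0.0);
  for (int i = 0; i < nb; ++i) bn[i] = b[i] / a0;
  for (int i = 0; i < na; ++i) an[i] = a[i] / a0;
  NumericMatrix Y(n, m);
  std::vector<double> z(nz);
  for (int j = 0; j < m; ++j) {
    std::fill(z.begin(), z.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      const double x = X(i, j);
      const double y = bn[0] * x + (nz ? z[0] : 0.0);
      for (int k = 0; k < nz - 1; ++k)
        z[k] = bn[k + 1] * x + z[k + 1] - an[k + 1] * y;
      if (nz) z[nz - 1] = bn[nz] * x - an[nz] * y;
      Y(i, j) = y;
    }
  }
  return Y;
}
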