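#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter, y[n] = (b*x - a[2:]*y)[n] / a[1].
// Single pass, zero initial state; used twice (forward/backward) by
// zero_phase_apply() after edge padding.
// [[Rcpp::export]]
NumericVector iir_filter_cpp(NumericVector b, NumericVector a, NumericVector x) {
  int nb = b.size(), na = a.size(), n = x.size();
  int nz = std::max(nb, na) - 1;
  std::vector<double> z(nz, 0.0), bb(nz + 1, 0.0), aa(nz + 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i] / a[0];
  for (int i = 0; i < na; ++i) aa[i] = a[i] / a[0];
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = bb[0] * xi + z[0];
    for (int k = 0; k < nz - 1; ++k) z[k] = bb[k + 1] * xi + z[k + 1] - aa[k + 1] * yi;
    z[nz - 1] = bb[nz] * xi - aa[nz] * yi;
    y[i] = yi;
  }
  return y;
}
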