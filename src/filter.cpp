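#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter, the inner loop of all zero-phase
// filtering in the package. Coefficients are normalized by a[0].
// [[Rcpp::export]]
NumericVector iir_filter_cpp(NumericVector b, NumericVector a,
                             NumericVector x) {
  int nb = b.size(), na = a.size(), n = x.size();
  int nfilt = std::max(nb, na);
  std::vector<double> bn(nfilt, 0.0), an(nfilt, 0.0);
  double a0 = a[0];
  for (int i = 0; i < nb; ++i) bn[i] = b[i] / a0;
  for (int i = 0; i < na; ++i) an[i] = a[i] / a0;
  std::vector<double> z(nfilt, 0.0);
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = bn[0] * xi + z[0];
    for (int j = 0; j < nfilt - 1; ++j)
      z[j] = bn[j + 1] * xi + z[j + 1] - an[j + 1] * yi;
    y[i] = yi;
  }
  return y;
}
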