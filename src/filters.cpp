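#include <Rcpp.h>
using namespace Rcpp;

// Direct-form-II-transposed IIR filter; a[0] must be 1 (as returned by
// signal::butter).
// [[Rcpp::export]]
NumericVector iir_filter_cpp(NumericVector b, NumericVector a,
                             NumericVector x) {
  const int n = x.size();
  const int nb = b.size();
  const int na = a.size();
  const int nw = std::max(nb, na);
  std::vector<double> w(nw, 0.0);
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = b[0] * xi + w[0];
    for (int k = 1; k < nw; ++k) {
      const double bk = (k < nb) ? b[k] : 0.0;
      const double ak = (k < na) ? a[k] : 0.0;
      w[k - 1] = bk * xi - ak * yi + ((k < nw - 1) ? w[k] : 0.0);
    }
    y[i] = yi;
  }
  return y;
}
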