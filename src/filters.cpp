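#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter with initial state zi (length n-1,
// already scaled by the caller). a[0] is assumed to be 1.
// [[Rcpp::export(name = ".lfilter_cpp")]]
NumericVector lfilter_cpp(NumericVector b, NumericVector a, NumericVector x,
                          NumericVector zi) {
  const int n = b.size();          // n == a.size()
  const int m = x.size();
  NumericVector y(m);
  std::vector<double> z(zi.begin(), zi.end());  // length n-1
  for (int i = 0; i < m; ++i) {
    double xi = x[i];
    double yi = b[0] * xi + (n > 1 ? z[0] : 0.0);
    for (int k = 0; k < n - 2; ++k)
      z[k] = b[k + 1] * xi + z[k + 1] - a[k + 1] * yi;
    if (n > 1)
      z[n - 2] = b[n - 1] * xi - a[n - 1] * yi;
    y[i] = yi;
  }
  return y;
}
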