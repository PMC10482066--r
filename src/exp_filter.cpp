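#include <Rcpp.h>
using namespace Rcpp;

// First-order exponential-kernel recursion applied down each column:
//   y[0] = 0;  y[i] = a*y[i-1] + (r - a)*x[i-1] + (1 - r)*x[i]
// which is the exact convolution of the piecewise-linear interpolant of x
// with the kernel exp(-u/phi)/phi on a uniform grid, where a = exp(-dt/phi)
// and r = (phi/dt)*(1 - a).
// [[Rcpp::export]]
NumericMatrix exp_filter_cpp(NumericMatrix x, double a, double r) {
  const int n = x.nrow(), K = x.ncol();
  NumericMatrix y(n, K);
  const double c0 = r - a, c1 = 1.0 - r;
  for (int k = 0; k < K; ++k) {
    const double* xc = &x(0, k);
    double* yc = &y(0, k);
    double prev = 0.0;
    yc[0] = 0.0;
    for (int i = 1; i < n; ++i) {
      prev = a * prev + c0 * xc[i - 1] + c1 * xc[i];
      yc[i] = prev;
    }
  }
  return y;
}
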