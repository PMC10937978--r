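#include <Rcpp.h>
using namespace Rcpp;

// Normalized LMS adaptive line enhancer.
// Predicts x[t] from the delayed tap vector x[t-delay .. t-delay-L+1]; the
// prediction y picks up the sample-correlated (tonal) content, the residual
// e = x - y the uncorrelated noise.
// [[Rcpp::export(name = ".nlms_run")]]
List nlms_run(NumericVector x, int L, double mu, int delay, double eps) {
  const int n = x.size();
  NumericVector y(n), e(n);
  std::vector<double> w(L, 0.0);
  for (int t = 0; t < n; ++t) {
    // tap vector u[k] = x[t - delay - k], k = 0..L-1
    double yt = 0.0, norm = eps;
    const int base = t - delay;
    for (int k = 0; k < L; ++k) {
      const int idx = base - k;
      if (idx < 0) break;
      const double u = x[idx];
      yt += w[k] * u;
      norm += u * u;
    }
    y[t] = yt;
    const double et = x[t] - yt;
    e[t] = et;
    const double g = mu * et / norm;
    for (int k = 0; k < L; ++k) {
      const int idx = base - k;
      if (idx < 0) break;
      w[k] += g * x[idx];
    }
  }
  return List::create(_["y"] = y, _["e"] = e);
}
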