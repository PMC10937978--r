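#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Soft-margin SVM dual solver with RBF kernel: sequential minimal
// optimization with maximal-violating-pair working-set selection and a
// duality-gap stopping rule (robust to duplicated feature rows, which are
// common for integer count features).

static inline double rbf(const NumericMatrix &X, int i, int j, double gamma) {
  double s = 0.0;
  const int d = X.ncol();
  for (int k = 0; k < d; ++k) {
    const double diff = X(i, k) - X(j, k);
    s += diff * diff;
  }
  return std::exp(-gamma * s);
}

// [[Rcpp::export(name = ".smo_fit")]]
List smo_fit(NumericMatrix X, NumericVector y, NumericVector w, double C,
             double gamma, double tol, int max_iter) {
  const int n = X.nrow();
  std::vector<double> Cw(n);
  for (int t = 0; t < n; ++t) Cw[t] = C * w[t];
  NumericMatrix K(n, n);
  for (int i = 0; i < n; ++i) {
    K(i, i) = 1.0;
    for (int j = i + 1; j < n; ++j) K(i, j) = K(j, i) = rbf(X, i, j, gamma);
  }
  std::vector<double> alpha(n, 0.0), G(n, -1.0); // G_i = d f / d alpha_i
  if (max_iter <= 0) max_iter = 40 * n;
  int iter = 0;
  double m_up = 0, m_dn = 0;
  for (iter = 0; iter < max_iter; ++iter) {
    // working-set selection: max violator i, second-order choice of j
    int i = -1, j = -1;
    m_up = -INFINITY;
    m_dn = INFINITY;
    for (int t = 0; t < n; ++t) {
      const double yg = -y[t] * G[t];
      const bool in_up = (y[t] > 0 && alpha[t] < Cw[t]) || (y[t] < 0 && alpha[t] > 0);
      const bool in_dn = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < Cw[t]);
      if (in_up && yg > m_up) { m_up = yg; i = t; }
      if (in_dn && yg < m_dn) m_dn = yg;
    }
    if (i < 0 || m_up - m_dn < tol) break;
    double best_obj = 0.0;
    for (int t = 0; t < n; ++t) {
      const bool in_dn = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < Cw[t]);
      if (!in_dn) continue;
      const double bt = m_up - (-y[t] * G[t]);
      if (bt <= 0) continue;
      double at = K(i, i) + K(t, t) - 2.0 * K(i, t);
      if (at <= 1e-12) at = 1e-12;
      const double objv = -bt * bt / at;
      if (objv < best_obj) { best_obj = objv; j = t; }
    }
    if (j < 0) break;
    // two-variable subproblem on (i, j)
    double eta = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (eta <= 1e-12) eta = 1e-12;
    // step along (y_i e_i - y_j e_j) for this pair's violation
    const double delta = (m_up - (-y[j] * G[j])) / eta;
    // box constraints
    double step = delta;
    if (y[i] > 0) step = std::min(step, Cw[i] - alpha[i]);
    else step = std::min(step, alpha[i]);
    if (y[j] > 0) step = std::min(step, alpha[j]);
    else step = std::min(step, Cw[j] - alpha[j]);
    if (step <= 0) break; // numerically stuck
    // feasible update: alpha_i += y_i d, alpha_j -= y_j d keeps y'alpha = 0
    alpha[i] += y[i] * step;
    alpha[j] -= y[j] * step;
    if (alpha[i] < 0) alpha[i] = 0; else if (alpha[i] > Cw[i]) alpha[i] = Cw[i];
    if (alpha[j] < 0) alpha[j] = 0; else if (alpha[j] > Cw[j]) alpha[j] = Cw[j];
    for (int t = 0; t < n; ++t)
      G[t] += step * y[t] * (K(i, t) - K(j, t));
  }
  // threshold from the violating-pair bounds
  double b = 0.5 * (m_up + m_dn);
  if (!std::isfinite(b)) b = 0.0;
  std::vector<int> sv;
  for (int t = 0; t < n; ++t) if (alpha[t] > 1e-12) sv.push_back(t);
  const int m = sv.size();
  NumericMatrix SV(m, X.ncol());
  NumericVector coef(m);
  for (int k = 0; k < m; ++k) {
    for (int c = 0; c < X.ncol(); ++c) SV(k, c) = X(sv[k], c);
    coef[k] = alpha[sv[k]] * y[sv[k]];
  }
  return List::create(_["sv"] = SV, _["coef"] = coef, _["b"] = b,
                      _["epochs"] = iter, _["n_sv"] = m);
}

// [[Rcpp::export(name = ".smo_decision")]]
NumericVector smo_decision(NumericMatrix SV, NumericVector coef, double b,
                           double gamma, NumericMatrix X) {
  const int n = X.nrow(), m = SV.nrow(), d = X.ncol();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double s = -b;
    for (int k = 0; k < m; ++k) {
      double q = 0.0;
      for (int c = 0; c < d; ++c) {
        const double diff = X(i, c) - SV(k, c);
        q += diff * diff;
      }
      s += coef[k] * std::exp(-gamma * q);
    }
    out[i] = s;
  }
  return out;
}
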