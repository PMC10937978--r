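#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Constrained Viterbi ridge tracker over a log-emission matrix (I bins x J
// columns). Per-column moves are limited to |n - i| < rho; transitions are
// uniform inside that neighbourhood, zero outside, so the optimal path
// maximizes the summed log emissions. Among equal-score paths the
// lexicographically smallest bin sequence is returned (lowest bin, then
// earliest divergence), via a backward DP and a greedy forward pass.
// Bins returned are 0-based.
// [[Rcpp::export(name = ".viterbi_path")]]
List viterbi_path(NumericMatrix logE, int rho) {
  const int I = logE.nrow(), J = logE.ncol();
  NumericMatrix B(I, J); // best suffix score starting at (i, j)
  for (int i = 0; i < I; ++i) B(i, J - 1) = logE(i, J - 1);
  for (int j = J - 2; j >= 0; --j) {
    for (int i = 0; i < I; ++i) {
      double best = -INFINITY;
      const int lo = std::max(0, i - rho + 1), hi = std::min(I - 1, i + rho - 1);
      for (int n = lo; n <= hi; ++n)
        if (B(n, j + 1) > best) best = B(n, j + 1);
      B(i, j) = logE(i, j) + best;
    }
  }
  IntegerVector path(J);
  const double tie = 1e-12;
  double best = -INFINITY;
  int cur = 0;
  for (int i = 0; i < I; ++i)
    if (B(i, 0) > best + tie) { best = B(i, 0); cur = i; }
  path[0] = cur;
  const double score = best;
  for (int j = 1; j < J; ++j) {
    const int lo = std::max(0, cur - rho + 1), hi = std::min(I - 1, cur + rho - 1);
    int nxt = -1; double bestn = -INFINITY;
    for (int n = lo; n <= hi; ++n)
      if (B(n, j) > bestn + tie) { bestn = B(n, j); nxt = n; }
    // guard: keep on an optimal continuation (bestn should equal remaining)
    cur = nxt;
    path[j] = cur;
  }
  return List::create(_["bins"] = path, _["score"] = score);
}
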