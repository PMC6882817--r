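// Exact permutation two-sided p-value for the Spearman rank correlation at
// small n: enumerate every distinct arrangement of the y-ranks with
// std::next_permutation.  With ties, each distinct arrangement of the rank
// multiset carries equal probability, so counting distinct arrangements is
// exact.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>

// [[Rcpp::export]]
double spearman_perm_p_cpp(Rcpp::NumericVector rx, Rcpp::NumericVector ry) {
  const int n = rx.size();
  std::vector<double> x(rx.begin(), rx.end());
  std::vector<double> y(ry.begin(), ry.end());

  double mx = 0, my = 0;
  for (int i = 0; i < n; ++i) { mx += x[i]; my += y[i]; }
  mx /= n; my /= n;
  double sx = 0, sy = 0;
  for (int i = 0; i < n; ++i) {
    sx += (x[i] - mx) * (x[i] - mx);
    sy += (y[i] - my) * (y[i] - my);
  }
  if (sx < 1e-12 || sy < 1e-12) return NA_REAL; // constant series
  const double denom = std::sqrt(sx * sy);

  double obs = 0;
  for (int i = 0; i < n; ++i) obs += (x[i] - mx) * (y[i] - my);
  obs = std::abs(obs / denom);

  std::sort(y.begin(), y.end());
  long long total = 0, hits = 0;
  do {
    double s = 0;
    for (int i = 0; i < n; ++i) s += (x[i] - mx) * (y[i] - my);
    double rho = std::abs(s / denom);
    ++total;
    if (rho >= obs - 1e-12) ++hits;
  } while (std::next_permutation(y.begin(), y.end()));

  return (double)hits / (double)total;
}
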