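// Artificial-centering hit-and-run in null-space coordinates.
// The flux polytope {S v = 0, lb <= v <= ub} is parameterised as
// v = v0 + N u with N an orthonormal null-space basis of S, so every chain
// state satisfies mass balance to machine precision; only the box bounds
// constrain the line search.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
arma::mat achr_sample_cpp(const arma::mat &N, const arma::vec &v0,
                          const arma::vec &lb, const arma::vec &ub,
                          const arma::mat &warmup_u, int n_samples,
                          int thin) {
  const uword n = v0.n_elem, k = N.n_cols;
  const uword n_store = warmup_u.n_cols;
  mat pool = warmup_u;               // points the direction draws mix over
  vec center = mean(pool, 1);
  vec u = center;                    // current chain state
  mat out(n, (uword)n_samples);
  const double tol = 1e-10;
  uword n_seen = n_store;

  for (int s = 0; s < n_samples; ++s) {
    for (int t = 0; t < thin; ++t) {
      uword pick = (uword)std::floor(R::runif(0.0, (double)n_store));
      if (pick >= n_store) pick = n_store - 1;
      vec d = pool.col(pick) - center;
      double nrm = norm(d);
      if (nrm < 1e-12) continue;
      d /= nrm;
      vec dv = N * d;                // direction in flux space
      vec v = v0 + N * u;
      // largest t-interval keeping lb <= v + t*dv <= ub
      double tmin = -datum::inf, tmax = datum::inf;
      for (uword i = 0; i < n; ++i) {
        double di = dv(i);
        if (std::abs(di) < tol) continue;
        double lo = (lb(i) - v(i)) / di;
        double hi = (ub(i) - v(i)) / di;
        if (di < 0) std::swap(lo, hi);
        if (lo > tmin) tmin = lo;
        if (hi < tmax) tmax = hi;
      }
      if (!std::isfinite(tmin) || !std::isfinite(tmax) || tmax <= tmin)
        continue;
      double step = R::runif(tmin, tmax);
      u += step * d;
      // artificial centering: running mean over all states visited
      n_seen++;
      center += (u - center) / (double)n_seen;
    }
    out.col((uword)s) = v0 + N * u;
  }
  return out;
}
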