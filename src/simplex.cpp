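// Dense two-phase primal simplex for small standard-form LPs:
//   min c'x  s.t.  A x = b,  x >= 0
// Sized for toy metabolic networks (hundreds of rows/cols), full-tableau
// arithmetic, Dantzig pricing with a Bland fallback for anti-cycling.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double EPS = 1e-9;

// Pivot the tableau T on (prow, pcol); basis bookkeeping done by caller.
static void pivot(mat &T, uword prow, uword pcol) {
  T.row(prow) /= T(prow, pcol);
  for (uword i = 0; i < T.n_rows; ++i) {
    if (i == prow) continue;
    double f = T(i, pcol);
    if (std::abs(f) > 0.0) T.row(i) -= f * T.row(prow);
  }
}

// One simplex phase on tableau T (m constraint rows + 1 cost row, last col
// rhs).  allowed[j] marks columns permitted to enter.  Returns 0 optimal,
// 2 unbounded, 3 iteration limit.
static int simplex_iterate(mat &T, uvec &basis, const std::vector<bool> &allowed,
                           int max_iter) {
  const uword m = T.n_rows - 1, ncol = T.n_cols - 1;
  int iter = 0;
  const int bland_after = max_iter / 2;
  while (iter++ < max_iter) {
    // entering column
    sword pcol = -1;
    if (iter < bland_after) {
      double best = -EPS;
      for (uword j = 0; j < ncol; ++j)
        if (allowed[j] && T(m, j) < best) { best = T(m, j); pcol = j; }
    } else { // Bland: first improving index
      for (uword j = 0; j < ncol; ++j)
        if (allowed[j] && T(m, j) < -EPS) { pcol = j; break; }
    }
    if (pcol < 0) return 0; // optimal
    // ratio test (tie -> smallest basis index, mild anti-cycling)
    sword prow = -1;
    double best_ratio = datum::inf;
    for (uword i = 0; i < m; ++i) {
      double a = T(i, pcol);
      if (a > EPS) {
        double r = T(i, ncol) / a;
        if (r < best_ratio - EPS ||
            (r < best_ratio + EPS && prow >= 0 && basis[i] < basis[(uword)prow])) {
          best_ratio = r; prow = i;
        }
      }
    }
    if (prow < 0) return 2; // unbounded
    pivot(T, (uword)prow, (uword)pcol);
    basis[(uword)prow] = (uword)pcol;
  }
  return 3;
}

// [[Rcpp::export]]
Rcpp::List lp_simplex_cpp(const arma::mat &A_in, const arma::vec &b_in,
                          const arma::vec &c, int max_iter = 20000) {
  mat A = A_in;
  vec b = b_in;
  const uword m = A.n_rows, n = A.n_cols;
  for (uword i = 0; i < m; ++i)
    if (b(i) < 0) { A.row(i) *= -1.0; b(i) *= -1.0; }

  // tableau: [A | I_artificial | rhs], plus cost row
  mat T(m + 1, n + m + 1, fill::zeros);
  T.submat(0, 0, m - 1, n - 1) = A;
  T.submat(0, n, m - 1, n + m - 1) = eye(m, m);
  T.col(n + m).head(m) = b;

  uvec basis(m);
  for (uword i = 0; i < m; ++i) basis(i) = n + i;

  // phase-1 cost row: minimize sum of artificials -> reduced costs are
  // -(column sums of A) on structural columns
  for (uword j = 0; j < n; ++j) T(m, j) = -accu(A.col(j));
  T(m, n + m) = -accu(b);

  std::vector<bool> allowed(n + m, false);
  for (uword j = 0; j < n; ++j) allowed[j] = true;

  int st = simplex_iterate(T, basis, allowed, max_iter);
  if (st == 3) return Rcpp::List::create(Rcpp::Named("status") = 3);
  double phase1 = -T(m, n + m);
  if (phase1 > 1e-7)
    return Rcpp::List::create(Rcpp::Named("status") = 1); // infeasible

  // drive basic artificials out where possible
  for (uword i = 0; i < m; ++i) {
    if (basis(i) >= n) {
      sword pc = -1;
      for (uword j = 0; j < n; ++j)
        if (std::abs(T(i, j)) > 1e-7) { pc = j; break; }
      if (pc >= 0) { pivot(T, i, (uword)pc); basis(i) = (uword)pc; }
      // else: redundant row; artificial stays basic at value 0
    }
  }

  // phase-2 cost row: rc_j = c_j - c_B' T[, j]
  vec cB(m);
  for (uword i = 0; i < m; ++i) cB(i) = basis(i) < n ? c(basis(i)) : 0.0;
  for (uword j = 0; j < n + m; ++j) {
    double cj = j < n ? c(j) : 0.0;
    T(m, j) = cj - dot(cB, T.col(j).head(m));
  }
  T(m, n + m) = -dot(cB, T.col(n + m).head(m));

  std::fill(allowed.begin() + n, allowed.end(), false); // bar artificials
  st = simplex_iterate(T, basis, allowed, max_iter);
  if (st != 0) return Rcpp::List::create(Rcpp::Named("status") = st);

  vec x(n, fill::zeros);
  for (uword i = 0; i < m; ++i)
    if (basis(i) < n) x(basis(i)) = T(i, n + m);
  return Rcpp::List::create(Rcpp::Named("status") = 0,
                            Rcpp::Named("x") = x,
                            Rcpp::Named("obj") = dot(c, x));
}
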