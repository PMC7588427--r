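// Simplex-constrained least squares:  min ||A x - b||^2  s.t.  x >= 0, sum(x) = 1.
//
// Active-set method in the style of Lawson-Hanson NNLS. The equality
// constraint is kept exactly by solving the KKT system restricted to the
// passive set at every inner step, so iterates always live on the simplex.
// Passive sets stay small (at most rank(A)+1), which is what makes the
// archetypal columns sparse.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static vec solve_kkt(const mat& A, const std::vector<uword>& P, const vec& b) {
  const uword p = P.size();
  mat Ap(A.n_rows, p);
  for (uword i = 0; i < p; ++i) Ap.col(i) = A.col(P[i]);
  mat M(p + 1, p + 1, fill::zeros);
  M.submat(0, 0, p - 1, p - 1) = Ap.t() * Ap;
  M.submat(0, p, p - 1, p).ones();
  M.submat(p, 0, p, p - 1).ones();
  vec rhs(p + 1);
  rhs.head(p) = Ap.t() * b;
  rhs(p) = 1.0;
  vec sol;
  if (!solve(sol, M, rhs, solve_opts::no_approx)) {
    // nearly singular passive block: fall back to a damped system
    M.submat(0, 0, p - 1, p - 1).diag() += 1e-10 * (1.0 + M.diag().max());
    sol = solve(M, rhs);
  }
  return sol.head(p);
}

static vec simplex_ls_one(const mat& A, const vec& b, double tol) {
  const uword n = A.n_cols;
  vec x(n, fill::zeros);
  if (n == 1) { x(0) = 1.0; return x; }

  // start from the single closest vertex (feasible)
  vec d2(n);
  for (uword j = 0; j < n; ++j) {
    vec r = A.col(j) - b;
    d2(j) = dot(r, r);
  }
  std::vector<uword> P;
  P.push_back(d2.index_min());
  x(P[0]) = 1.0;

  const int max_outer = 3 * static_cast<int>(n) + 30;
  for (int outer = 0; outer < max_outer; ++outer) {
    // inner loop: solve on the passive set, dropping variables that go negative
    for (uword inner = 0; inner < 2 * n + 10; ++inner) {
      vec z = solve_kkt(A, P, b);
      if (z.min() >= -tol) {
        x.zeros();
        double s = 0.0;
        for (uword i = 0; i < P.size(); ++i) {
          double v = std::max(z(i), 0.0);
          x(P[i]) = v;
          s += v;
        }
        if (s <= 0) { x(P[0]) = 1.0; s = 1.0; }
        for (uword i = 0; i < P.size(); ++i) x(P[i]) /= s;
        break;
      }
      // step from x toward z until the first passive coordinate hits zero
      double alpha = 1.0;
      for (uword i = 0; i < P.size(); ++i) {
        if (z(i) < 0) {
          double xi = x(P[i]);
          double a = xi / (xi - z(i));
          if (a < alpha) alpha = a;
        }
      }
      std::vector<uword> keep;
      double s = 0.0;
      for (uword i = 0; i < P.size(); ++i) {
        double v = (1.0 - alpha) * x(P[i]) + alpha * z(i);
        x(P[i]) = v;
        if (v > tol) { keep.push_back(P[i]); s += v; }
        else x(P[i]) = 0.0;
      }
      if (keep.empty()) { keep.push_back(P[0]); x(P[0]) = 1.0; s = 1.0; }
      for (uword i : keep) x(i) /= s;
      for (uword j = 0; j < n; ++j)
        if (std::find(keep.begin(), keep.end(), j) == keep.end()) x(j) = 0.0;
      P = keep;
    }

    // optimality: with multiplier lambda = -g on the passive set, an active
    // coordinate can only improve the fit if its gradient drops below the
    // passive-set gradient level
    vec g = A.t() * (A * x - b);
    double g_pass = datum::inf;
    for (uword i : P) g_pass = std::min(g_pass, g(i));
    double slack = tol * std::max(1.0, std::abs(g_pass));
    uword best = n;
    double best_g = g_pass - slack;
    for (uword j = 0; j < n; ++j) {
      if (x(j) > 0) continue;
      if (g(j) < best_g) { best_g = g(j); best = j; }
    }
    if (best == n) break;
    P.push_back(best);
  }
  return x;
}

// [[Rcpp::export]]
arma::mat cpp_simplex_ls(const arma::mat& A, const arma::mat& B, double tol = 1e-10) {
  mat X(A.n_cols, B.n_cols);
  for (uword j = 0; j < B.n_cols; ++j) X.col(j) = simplex_ls_one(A, B.col(j), tol);
  return X;
}
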