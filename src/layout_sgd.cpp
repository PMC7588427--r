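// Stochastic gradient layout of a weighted cell network.
//
// Minimizes the fuzzy cross-entropy between the graph's edge affinities and
// the low-dimensional kernel f(d) = 1 / (1 + a d^{2b}) with per-edge
// attractive updates and uniformly sampled repulsive (negative) updates.
// Edge sampling frequency is proportional to edge weight, as in the standard
// SGD embedding schedule. Single-threaded and fully determined by `seed`.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double clamp4(double v) {
  if (v > 4.0) return 4.0;
  if (v < -4.0) return -4.0;
  return v;
}

// [[Rcpp::export]]
arma::mat cpp_layout_sgd(arma::mat coords,
                         const arma::uvec& head,
                         const arma::uvec& tail,
                         const arma::vec& weight,
                         double a, double b,
                         int epochs, double lr0,
                         int neg_rate, int seed) {
  const uword n = coords.n_rows;
  const uword dims = coords.n_cols;
  const uword m = head.n_elem;

  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::uniform_int_distribution<uword> pick(0, n - 1);

  const double wmax = weight.max();
  vec eps(m), next_s(m), eps_neg(m), next_neg(m);
  for (uword e = 0; e < m; ++e) {
    eps(e) = wmax / weight(e);           // epochs between samples of edge e
    next_s(e) = eps(e);
    eps_neg(e) = eps(e) / std::max(neg_rate, 1);
    next_neg(e) = eps_neg(e);
  }

  std::vector<double> diff(dims);
  for (int epoch = 1; epoch <= epochs; ++epoch) {
    const double lr = lr0 * (1.0 - (epoch - 1.0) / epochs);
    for (uword e = 0; e < m; ++e) {
      if (next_s(e) > epoch) continue;
      const uword i = head(e), j = tail(e);

      double d2 = 0.0;
      for (uword t = 0; t < dims; ++t) {
        diff[t] = coords(i, t) - coords(j, t);
        d2 += diff[t] * diff[t];
      }
      if (d2 > 0.0) {
        const double pd = std::pow(d2, b);
        const double gc = (-2.0 * a * b * pd / d2) / (a * pd + 1.0);
        for (uword t = 0; t < dims; ++t) {
          const double g = clamp4(gc * diff[t]) * lr;
          coords(i, t) += g;
          coords(j, t) -= g;
        }
      }
      next_s(e) += eps(e);

      const int n_neg = static_cast<int>((epoch - (next_neg(e) - eps_neg(e))) / eps_neg(e));
      for (int s = 0; s < n_neg; ++s) {
        const uword k = pick(rng);
        if (k == i) continue;
        double r2 = 0.0;
        for (uword t = 0; t < dims; ++t) {
          diff[t] = coords(i, t) - coords(k, t);
          r2 += diff[t] * diff[t];
        }
        const double pd = std::pow(r2, b);
        const double gc = (2.0 * b) / ((0.001 + r2) * (a * pd + 1.0));
        for (uword t = 0; t < dims; ++t) {
          double g = (r2 > 0.0) ? clamp4(gc * diff[t]) : 4.0;
          coords(i, t) += g * lr;
        }
      }
      next_neg(e) += n_neg * eps_neg(e);
    }
  }
  return coords;
}
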