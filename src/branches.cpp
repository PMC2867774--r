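#include <Rcpp.h>
#include <cmath>
#include <vector>

// falling-factorial binomial C(x, l) extended to real x, clamped at 0
static inline double fbinom(double x, int l) {
  if (l == 0) return 1.0;
  double out = 1.0;
  for (int i = 0; i < l; ++i) out *= (x - i);
  for (int i = 2; i <= l; ++i) out /= i;
  return out > 0 ? out : 0.0;
}

// Advance all worst-case deterministic branch trajectories by up to
// `max_rounds` shared steps (step length = 1 / max exit rate over the
// trajectories, capped by the remaining time budget). Mass-action networks
// only: V is the k x n change matrix, L the k x n reactant multiplicities.
// Returns the updated trajectories, the per-dimension envelope of all
// intermediate states, the elapsed time, and whether every trajectory was
// absorbing (nothing could move).
// [[Rcpp::export]]
Rcpp::List branch_rounds_ma(Rcpp::NumericMatrix X, Rcpp::LogicalMatrix more,
                            Rcpp::LogicalMatrix fewer, Rcpp::NumericMatrix V,
                            Rcpp::NumericVector rates, Rcpp::IntegerMatrix L,
                            double t_limit, int max_rounds) {
  const int T = X.nrow(), n = X.ncol(), k = rates.size();
  std::vector<double> lo(n, R_PosInf), hi(n, R_NegInf);
  std::vector<double> a(k);
  double elapsed = 0.0;
  bool all_absorbing = false;
  Rcpp::NumericMatrix Xw(Rcpp::clone(X));
  for (int round = 0; round < max_rounds; ++round) {
    if (elapsed >= t_limit) break;
    // propensities and the fastest exit rate over all trajectories
    double lam_max = 0.0;
    std::vector<double> A(T * k);
    for (int t = 0; t < T; ++t) {
      double lam = 0.0;
      for (int m = 0; m < k; ++m) {
        double am = rates[m];
        for (int i = 0; i < n && am > 0; ++i)
          if (L(m, i) > 0) am *= fbinom(Xw(t, i), L(m, i));
        A[t * k + m] = am;
        lam += am;
      }
      if (lam > lam_max) lam_max = lam;
    }
    if (lam_max <= 0.0) { all_absorbing = true; break; }
    double d = 1.0 / lam_max;
    if (d > t_limit - elapsed) d = t_limit - elapsed;
    for (int t = 0; t < T; ++t) {
      for (int m = 0; m < k; ++m) {
        double e = A[t * k + m] * d;
        double s = std::sqrt(e);
        double kap = e;
        if (more(t, m)) kap += s;
        else if (fewer(t, m)) kap -= s;
        if (kap < 0) kap = 0;
        a[m] = kap;
      }
      for (int i = 0; i < n; ++i) {
        double x = Xw(t, i);
        for (int m = 0; m < k; ++m) x += a[m] * V(m, i);
        if (x < 0) x = 0;
        Xw(t, i) = x;
        if (x < lo[i]) lo[i] = x;
        if (x > hi[i]) hi[i] = x;
      }
    }
    elapsed += d;
  }
  return Rcpp::List::create(
      Rcpp::Named("X") = Xw, Rcpp::Named("lower") = Rcpp::wrap(lo),
      Rcpp::Named("upper") = Rcpp::wrap(hi),
      Rcpp::Named("elapsed") = elapsed,
      Rcpp::Named("all_absorbing") = all_absorbing);
}
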