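#include <Rcpp.h>
#include <vector>

// Uniformization inner loop: given the DTMC matrix P = I + Q/lambda in
// compressed sparse column form, the initial row vector p0, and Poisson
// weights for steps L..U, accumulate sum_{k=L..U} w_k * p0 P^k on the fly.
// Entries below `prune` are dropped from the running vector to preserve
// sparsity of the iterates.
// [[Rcpp::export]]
Rcpp::NumericVector unif_core(Rcpp::IntegerVector Pp, Rcpp::IntegerVector Pi,
                              Rcpp::NumericVector Px, Rcpp::NumericVector p0,
                              Rcpp::NumericVector weights, int L,
                              double prune) {
  const int n = p0.size();
  const int U = L + weights.size() - 1;
  const int *pp = Pp.begin();
  const int *pi = Pi.begin();
  const double *px = Px.begin();
  const double *wt = weights.begin();
  std::vector<double> w(p0.begin(), p0.end()), wn(n);
  std::vector<double> acc(n, 0.0);
  if (L == 0) {
    const double w0 = wt[0];
    for (int i = 0; i < n; ++i) acc[i] += w0 * w[i];
  }
  for (int k = 1; k <= U; ++k) {
    const double *wv = w.data();
    double *out = wn.data();
    for (int j = 0; j < n; ++j) {
      double s = 0.0;
      const int end = pp[j + 1];
      for (int idx = pp[j]; idx < end; ++idx) s += wv[pi[idx]] * px[idx];
      out[j] = (s < prune) ? 0.0 : s;
    }
    std::swap(w, wn);
    if (k >= L) {
      const double wk = wt[k - L];
      const double *wv2 = w.data();
      for (int i = 0; i < n; ++i) acc[i] += wk * wv2[i];
    }
    if ((k & 8191) == 0) Rcpp::checkUserInterrupt();
  }
  return Rcpp::NumericVector(acc.begin(), acc.end());
}
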