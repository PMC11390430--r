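#include <Rcpp.h>
using namespace Rcpp;

// Unconstrained DTW with |x_i - y_j| step cost, steps {down, right, diagonal},
// boundary-anchored, unnormalized accumulated cost. Two-row DP keeps memory
// at O(min footprint) for long LFP traces.
// [[Rcpp::export(name = ".dtw_cost")]]
double dtw_cost(NumericVector x, NumericVector y) {
  const int n = x.size(), m = y.size();
  if (n == 0 || m == 0)
    stop("DTW is undefined for empty sequences");
  std::vector<double> prev(m), curr(m);
  prev[0] = std::abs(x[0] - y[0]);
  for (int j = 1; j < m; ++j) prev[j] = prev[j - 1] + std::abs(x[0] - y[j]);
  for (int i = 1; i < n; ++i) {
    curr[0] = prev[0] + std::abs(x[i] - y[0]);
    for (int j = 1; j < m; ++j) {
      double best = std::min(prev[j], std::min(curr[j - 1], prev[j - 1]));
      curr[j] = best + std::abs(x[i] - y[j]);
    }
    std::swap(prev, curr);
  }
  return prev[m - 1];
}

// Draws i.i.d. uniform categories 1..c until k distinct categories have been
// seen; repeats n_runs times and returns the draw counts. Uses R's RNG so
// set.seed() governs reproducibility.
// [[Rcpp::export(name = ".coupon_draws")]]
NumericVector coupon_draws(int c, int k, int n_runs) {
  if (c < 1 || k < 1 || k > c || n_runs < 1)
    stop("invalid coupon-collector parameters");
  NumericVector out(n_runs);
  std::vector<char> seen(c);
  for (int r = 0; r < n_runs; ++r) {
    std::fill(seen.begin(), seen.end(), 0);
    int distinct = 0;
    double draws = 0.0;
    while (distinct < k) {
      int cat = (int)(unif_rand() * c);
      if (cat >= c) cat = c - 1; // guard against unif_rand() == 1.0
      ++draws;
      if (!seen[cat]) { seen[cat] = 1; ++distinct; }
    }
    out[r] = draws;
  }
  return out;
}
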