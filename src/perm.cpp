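#include <Rcpp.h>
#include <numeric>
using namespace Rcpp;

// Null distribution of the mean difference (after - before) under datapoint
// shuffling between the two traces. Partial Fisher-Yates per permutation:
// only the first n_before positions need to be drawn to fix the bipartition.
// Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
NumericVector perm_mean_diffs(NumericVector pooled, int n_before,
                              int n_perm) {
  int n = pooled.size();
  if (n_before <= 0 || n_before >= n)
    stop("n_before must be strictly between 0 and length(pooled)");
  std::vector<double> w(pooled.begin(), pooled.end());
  NumericVector out(n_perm);
  double total = std::accumulate(w.begin(), w.end(), 0.0);
  int n_after = n - n_before;
  for (int p = 0; p < n_perm; ++p) {
    double s_b = 0.0;
    for (int i = 0; i < n_before; ++i) {
      int j = i + (int)(unif_rand() * (n - i));
      if (j >= n) j = n - 1;
      std::swap(w[i], w[j]);
      s_b += w[i];
    }
    out[p] = (total - s_b) / n_after - s_b / n_before;
  }
  return out;
}
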