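#include <Rcpp.h>
#include <algorithm>
#include <vector>

// Exact permutation distribution of the Spearman statistic S = sum(rx * ry)
// over all arrangements of rx against ry. Ties are handled by enumerating
// the distinct arrangements of the (possibly tied) rank vector with
// std::next_permutation: every distinct arrangement corresponds to the same
// number of underlying permutations, so uniform weight over distinct
// arrangements equals the permutation distribution. Feasible for n <= 10.

// [[Rcpp::export]]
Rcpp::NumericVector spearman_perm_counts(Rcpp::NumericVector rx,
                                         Rcpp::NumericVector ry,
                                         double s_obs, double tol) {
  int n = rx.size();
  std::vector<double> x(rx.begin(), rx.end());
  std::sort(x.begin(), x.end());
  double sum_x = 0.0, sum_y = 0.0;
  for (int i = 0; i < n; ++i) { sum_x += x[i]; sum_y += ry[i]; }
  double s_mean = sum_x * sum_y / n;  // E[S] under permutation
  double dev_obs = std::fabs(s_obs - s_mean);

  double n_total = 0.0, n_ge = 0.0, n_le = 0.0, n_abs = 0.0;
  do {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += x[i] * ry[i];
    n_total += 1.0;
    if (s >= s_obs - tol) n_ge += 1.0;
    if (s <= s_obs + tol) n_le += 1.0;
    if (std::fabs(s - s_mean) >= dev_obs - tol) n_abs += 1.0;
  } while (std::next_permutation(x.begin(), x.end()));

  return Rcpp::NumericVector::create(n_total, n_ge, n_le, n_abs);
}
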