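#include <Rcpp.h>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Dynamic time warping cost with |x_i - y_j| local cost and the symmetric
// step pattern (match / insert / delete, unweighted). A Sakoe-Chiba band of
// half-width `band` restricts evaluation to |i - j| <= band; band < 0 means
// the full matrix. Infeasibility (band tighter than the length difference)
// is checked by the R wrapper.
// [[Rcpp::export(name = ".dtw_cost")]]
double dtw_cost(NumericVector x, NumericVector y, int band) {
  const int n = x.size(), m = y.size();
  const double inf = std::numeric_limits<double>::infinity();
  std::vector<double> prev(m + 1, inf), cur(m + 1, inf);
  prev[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    std::fill(cur.begin(), cur.end(), inf);
    int jlo = 1, jhi = m;
    if (band >= 0) {
      jlo = std::max(1, i - band);
      jhi = std::min(m, i + band);
    }
    for (int j = jlo; j <= jhi; ++j) {
      double c = std::fabs(x[i - 1] - y[j - 1]);
      double best = prev[j - 1];              // diagonal
      if (prev[j] < best) best = prev[j];     // insertion
      if (cur[j - 1] < best) best = cur[j - 1]; // deletion
      cur[j] = c + best;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}
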