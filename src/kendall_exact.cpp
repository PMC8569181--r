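#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// S = sum_{i<j} sign(x_i - x_j) * sign(y_i - y_j)
static long long s_statistic(const std::vector<double>& x,
                             const std::vector<double>& y) {
  const int n = x.size();
  long long s = 0;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double dx = x[i] - x[j], dy = y[i] - y[j];
      const int sx = (dx > 0) - (dx < 0), sy = (dy > 0) - (dy < 0);
      s += sx * sy;
    }
  }
  return s;
}

// Exact two-sided p-value for Kendall's S under the permutation null:
// enumerate every distinct arrangement of y (ties handled naturally, each
// distinct arrangement is equally likely) and count |S_perm| >= |S_obs|.
// Intended for small n (<= 10).
// [[Rcpp::export]]
double kendall_exact_pvalue_cpp(NumericVector x, NumericVector y) {
  const int n = x.size();
  if (n != y.size()) stop("x and y must have equal length");
  std::vector<double> xv(x.begin(), x.end());
  std::vector<double> yv(y.begin(), y.end());
  const long long s_obs = std::llabs(s_statistic(xv, yv));
  std::sort(yv.begin(), yv.end());
  long long total = 0, extreme = 0;
  do {
    ++total;
    if (std::llabs(s_statistic(xv, yv)) >= s_obs) ++extreme;
  } while (std::next_permutation(yv.begin(), yv.end()));
  return static_cast<double>(extreme) / static_cast<double>(total);
}
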