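#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Circular binary segmentation core.
//
// For a series x[0..n-1], the circular split statistic of the arc (i, j]
// (0 <= i < j <= n) compares the mean inside the arc with the mean outside:
//   U(i,j) = |S_j - S_i - k/n * S_n| * sqrt(n / (k * (n - k))),  k = j - i.
// U is sqrt of the between-group sum of squares of the binary split, so the
// arg-max arc is the least-squares-optimal circular split; U / sigma is the
// usual two-sample t numerator under a common noise sd sigma. Arcs longer
// than n/2 are redundant (the complement gives the same statistic), so the
// scan covers k <= n/2 only: O(n^2 / 2) with a trivial inner loop.

static void scan_max(const std::vector<double>& S, int n,
                     double& best, int& bi, int& bj, double stop_at) {
  const double tot = S[n];
  best = -1.0; bi = 0; bj = 0;
  const int gmax = n / 2;
  for (int g = 1; g <= gmax && g < n; ++g) {
    const double f = std::sqrt((double)n / ((double)g * (double)(n - g)));
    const double mean_g = tot * g / n;
    double mx = -1e300, mn = 1e300;
    int amx = 0, amn = 0;
    const int lim = n - g;
    for (int i = 0; i <= lim; ++i) {
      const double d = S[i + g] - S[i];
      if (d > mx) { mx = d; amx = i; }
      if (d < mn) { mn = d; amn = i; }
    }
    const double u1 = std::fabs(mx - mean_g) * f;
    const double u2 = std::fabs(mn - mean_g) * f;
    if (u1 > best) { best = u1; bi = amx; bj = amx + g; }
    if (u2 > best) { best = u2; bi = amn; bj = amn + g; }
    if (stop_at > 0 && best >= stop_at) return;  // early exit for permutations
  }
}

// Maximal circular split statistic of x.
// Returns u and the arc (i, j] as 0-based bin offsets: the arc covers bins
// i+1 .. j in 1-based terms; breakpoints fall after bin i and after bin j.
// [[Rcpp::export(name = ".cbs_scan")]]
List cbs_scan_cpp(NumericVector x) {
  const int n = x.size();
  std::vector<double> S(n + 1, 0.0);
  for (int i = 0; i < n; ++i) S[i + 1] = S[i] + x[i];
  double best; int bi, bj;
  scan_max(S, n, best, bi, bj, -1.0);
  return List::create(_["u"] = best, _["i"] = bi, _["j"] = bj);
}

// Permutation p-value for an observed maximal statistic, with sequential
// early stopping: once the exceedance count guarantees p > alpha the loop
// aborts. Uses R's RNG, so set.seed() upstream makes runs reproducible.
// [[Rcpp::export(name = ".cbs_perm")]]
List cbs_perm_cpp(NumericVector x, double uobs, int nperm, double alpha) {
  const int n = x.size();
  std::vector<double> y(x.begin(), x.end());
  std::vector<double> S(n + 1, 0.0);
  const int stop_at = (int)std::ceil(alpha * nperm);
  int exceed = 0, done = 0;
  for (int p = 0; p < nperm; ++p) {
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(y[i], y[j]);
    }
    for (int i = 0; i < n; ++i) S[i + 1] = S[i] + y[i];
    double best; int bi, bj;
    scan_max(S, n, best, bi, bj, uobs);
    ++done;
    if (best >= uobs) ++exceed;
    if (exceed > stop_at) break;
  }
  const double pval = (exceed + 1.0) / (done + 1.0);
  return List::create(_["p"] = pval, _["exceed"] = exceed,
                      _["nperm_done"] = done);
}
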