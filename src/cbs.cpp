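#include <Rcpp.h>
using namespace Rcpp;

// Circular binary segmentation inner loops.
//
// The arc statistic for an arc (i, j] of a series x[1..n] is the absolute
// standardized mean difference between the windows inside the arc and those
// outside it,
//     t(i, j) = |mean_in - mean_out| / sqrt(1/k + 1/(n - k)),  k = j - i.
// The within-series scale cancels in the permutation test (the permuted series
// has the same pooled variance), so it is left out here; callers that want an
// interpretable t divide by an SD estimate themselves.
//
// min_width applies to every segment a split would create: the arc itself and,
// when the arc does not touch a series end, both flanks.

static double arc_scan(const double *s, int n, int min_width,
                       int *best_i, int *best_j) {
  // s = prefix sums, s[0] = 0, s[n] = total
  double total = s[n];
  double tmax = -1.0;
  int bi = -1, bj = -1;
  for (int i = 0; i <= n - min_width; ++i) {
    if (i > 0 && i < min_width) continue;  // left flank too short
    for (int j = i + min_width; j <= n; ++j) {
      int k = j - i;
      if (k == n) break;                   // arc must leave something outside
      if (j < n && n - j < min_width) continue;  // right flank too short
      if (n - k < min_width) continue;     // outside too short
      double mean_in = (s[j] - s[i]) / k;
      double mean_out = (total - s[j] + s[i]) / (n - k);
      double t = std::fabs(mean_in - mean_out) /
                 std::sqrt(1.0 / k + 1.0 / (n - k));
      if (t > tmax + 1e-12) {  // ties broken by smallest (i, then j)
        tmax = t;
        bi = i;
        bj = j;
      }
    }
  }
  *best_i = bi;
  *best_j = bj;
  return tmax;
}

// [[Rcpp::export]]
List cbs_max_arc(NumericVector x, int min_width) {
  int n = x.size();
  std::vector<double> s(n + 1, 0.0);
  for (int i = 0; i < n; ++i) s[i + 1] = s[i] + x[i];
  int bi, bj;
  double tmax = arc_scan(s.data(), n, min_width, &bi, &bj);
  return List::create(_["i"] = bi, _["j"] = bj, _["t"] = tmax);
}

// Permutation p-value for the max arc statistic, with early termination once
// the exceedance count guarantees p >= alpha (the split is then rejected no
// matter how the remaining permutations fall). Uses R's RNG so results follow
// set.seed() on the R side.
// [[Rcpp::export]]
List cbs_perm_count(NumericVector x, int min_width, int n_perm, double t_obs,
                    double alpha) {
  int n = x.size();
  std::vector<double> perm(x.begin(), x.end());
  std::vector<double> s(n + 1, 0.0);
  int bi, bj;
  int exceed = 0, done = 0;
  double stop_at = alpha * (1.0 + n_perm) - 1.0;  // p=(1+exceed)/(1+n_perm)
  RNGScope scope;
  for (int p = 0; p < n_perm; ++p) {
    // Fisher-Yates shuffle
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(perm[i], perm[j]);
    }
    for (int i = 0; i < n; ++i) s[i + 1] = s[i] + perm[i];
    double t = arc_scan(s.data(), n, min_width, &bi, &bj);
    ++done;
    if (t >= t_obs - 1e-12) {
      ++exceed;
      if ((double)exceed >= stop_at) break;  // p cannot drop below alpha
    }
  }
  return List::create(_["exceed"] = exceed, _["done"] = done);
}
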