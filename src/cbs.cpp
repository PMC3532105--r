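#include <Rcpp.h>
using namespace Rcpp;

// Max circular-split statistic over all arc boundary pairs (i, j),
// 0 <= i < j <= n, arc = x[i+1..j] (1-based), complement = the rest.
// T(i,j) = |mean(arc) - mean(rest)| / (sigma * sqrt(1/k + 1/(n-k)))
// with k = arc length and sigma the SD of the whole segment (fixed),
// arc and complement each required to span >= minw markers.
static void scan_max(const NumericVector& x, int minw,
                     double& best, int& bi, int& bj) {
  int n = x.size();
  std::vector<double> cs(n + 1, 0.0);
  for (int t = 0; t < n; ++t) cs[t + 1] = cs[t] + x[t];
  double total = cs[n];
  best = -1.0; bi = 0; bj = 0;
  for (int i = 0; i < n; ++i) {
    double csi = cs[i];
    for (int j = i + 1; j <= n; ++j) {
      int k = j - i;
      if (k < minw || k > n - minw) continue;
      double sa = cs[j] - csi;
      double ma = sa / k;
      double mr = (total - sa) / (n - k);
      double t = std::fabs(ma - mr) / std::sqrt(1.0 / k + 1.0 / (n - k));
      if (t > best) { best = t; bi = i; bj = j; }
    }
  }
}

static double seg_sd(const NumericVector& x) {
  int n = x.size();
  double m = 0.0, s2 = 0.0;
  for (int t = 0; t < n; ++t) m += x[t];
  m /= n;
  for (int t = 0; t < n; ++t) s2 += (x[t] - m) * (x[t] - m);
  return std::sqrt(s2 / (n - 1));
}

// [[Rcpp::export(name = ".cbs_scan")]]
List cbs_scan_cpp(NumericVector x, int minw) {
  double best; int bi, bj;
  scan_max(x, minw, best, bi, bj);
  double sd = seg_sd(x);
  double stat = (best < 0 || sd <= 0) ? 0.0 : best / sd;
  return List::create(_["stat"] = stat,
                      _["i"] = bi,      // arc is (i+1)..j in 1-based marker index
                      _["j"] = bj,
                      _["found"] = best >= 0);
}

// Permutation p-value for the max split statistic, with early stopping:
// once the exceedance count makes p > alpha certain, stop.
// Uses R's RNG (seed with set.seed() on the R side).
// [[Rcpp::export(name = ".cbs_perm_test")]]
List cbs_perm_test_cpp(NumericVector x, int minw, int nperm, double alpha) {
  int n = x.size();
  double best; int bi, bj;
  scan_max(x, minw, best, bi, bj);
  double sd = seg_sd(x);
  if (best < 0 || sd <= 0) {
    return List::create(_["stat"] = 0.0, _["i"] = 0, _["j"] = 0,
                        _["p"] = 1.0, _["nperm_used"] = 0, _["found"] = false);
  }
  double obs = best;  // sigma identical across permutations; compare raw
  int exceed = 0, done = 0;
  // smallest exceedance count that already forces p > alpha
  int stop_at = (int)std::floor(alpha * (nperm + 1));
  NumericVector xp = clone(x);
  for (int b = 0; b < nperm; ++b) {
    // Fisher-Yates with R's RNG
    for (int t = n - 1; t > 0; --t) {
      int u = (int)(unif_rand() * (t + 1));
      if (u > t) u = t;
      std::swap(xp[t], xp[u]);
    }
    double pb; int pi, pj;
    scan_max(xp, minw, pb, pi, pj);
    ++done;
    if (pb >= obs) {
      ++exceed;
      if (exceed >= stop_at + 1) break;  // p must exceed alpha now
    }
  }
  double p = (1.0 + exceed) / (1.0 + done);
  return List::create(_["stat"] = obs / sd, _["i"] = bi, _["j"] = bj,
                      _["p"] = p, _["nperm_used"] = done, _["found"] = true);
}
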