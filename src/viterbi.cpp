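#include <Rcpp.h>
using namespace Rcpp;

// Viterbi decoding for a chain with per-step distance-dependent transition
// probabilities: at step t -> t+1 the chain changes state with probability
// pchange[t], split evenly over the other S-1 states.
// logem: m x S matrix of emission log-likelihoods; loginit: length-S.
// [[Rcpp::export(name = ".viterbi_decode")]]
List viterbi_decode_cpp(NumericMatrix logem, NumericVector loginit,
                        NumericVector pchange) {
  int m = logem.nrow(), S = logem.ncol();
  if (m == 0) stop("empty emission matrix");
  NumericMatrix delta(m, S);
  IntegerMatrix psi(m, S);
  for (int s = 0; s < S; ++s) delta(0, s) = loginit[s] + logem(0, s);
  for (int t = 1; t < m; ++t) {
    double p = pchange[t - 1];
    double lstay = std::log(1.0 - p);
    double lmove = std::log(p / (S - 1));
    for (int s = 0; s < S; ++s) {
      double best = R_NegInf; int arg = 0;
      for (int r = 0; r < S; ++r) {
        double v = delta(t - 1, r) + (r == s ? lstay : lmove);
        if (v > best) { best = v; arg = r; }
      }
      delta(t, s) = best + logem(t, s);
      psi(t, s) = arg;
    }
  }
  double best = R_NegInf; int arg = 0;
  for (int s = 0; s < S; ++s)
    if (delta(m - 1, s) > best) { best = delta(m - 1, s); arg = s; }
  IntegerVector path(m);
  path[m - 1] = arg;
  for (int t = m - 1; t > 0; --t) path[t - 1] = psi(t, path[t]);
  for (int t = 0; t < m; ++t) path[t] += 1;  // 1-based states for R
  return List::create(_["path"] = path, _["logprob"] = best);
}

// Independent oracle: exhaustive depth-first enumeration of all S^m state
// paths, keeping the best joint log-probability. Only feasible for tiny m;
// shares no recursion with the Viterbi DP above.
static void dfs(int t, double acc, int prev,
                const NumericMatrix& logem, const NumericVector& loginit,
                const NumericVector& pchange, int m, int S,
                double& best, std::vector<int>& cur, std::vector<int>& bestp) {
  if (t == m) {
    if (acc > best) { best = acc; bestp = cur; }
    return;
  }
  for (int s = 0; s < S; ++s) {
    double step;
    if (t == 0) step = loginit[s];
    else {
      double p = pchange[t - 1];
      step = (s == prev) ? std::log(1.0 - p) : std::log(p / (S - 1));
    }
    cur[t] = s;
    dfs(t + 1, acc + step + logem(t, s), s, logem, loginit, pchange,
        m, S, best, cur, bestp);
  }
}

// [[Rcpp::export(name = ".viterbi_brute_force")]]
List viterbi_brute_force_cpp(NumericMatrix logem, NumericVector loginit,
                             NumericVector pchange) {
  int m = logem.nrow(), S = logem.ncol();
  if (std::pow((double)S, (double)m) > 3e8)
    stop("instance too large for exhaustive enumeration");
  double best = R_NegInf;
  std::vector<int> cur(m), bestp(m);
  dfs(0, 0.0, -1, logem, loginit, pchange, m, S, best, cur, bestp);
  IntegerVector path(m);
  for (int t = 0; t < m; ++t) path[t] = bestp[t] + 1;
  return List::create(_["path"] = path, _["logprob"] = best);
}
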