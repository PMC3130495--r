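// Elastic distances on short 1-D index series: dynamic-programming
// implementations of DTW, LCSS and MVM, together with brute-force
// enumeration counterparts used as independent oracles in the test suite.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// ---------------------------------------------------------------- DTW -----
// Classic warping cost: local cost |x_i - y_j|, unconstrained window,
// symmetric step pattern (up, right, diagonal).
// [[Rcpp::export]]
double dtw_cpp(NumericVector x, NumericVector y) {
  int m = x.size(), n = y.size();
  if (m == 0 || n == 0) stop("dtw: empty series");
  std::vector<double> prev(n + 1, INF), cur(n + 1, INF);
  prev[0] = 0.0;
  for (int i = 1; i <= m; ++i) {
    cur[0] = INF;
    for (int j = 1; j <= n; ++j) {
      double c = std::fabs(x[i - 1] - y[j - 1]);
      double best = std::min(prev[j], std::min(cur[j - 1], prev[j - 1]));
      cur[j] = c + best;
    }
    std::swap(prev, cur);
  }
  return prev[n];
}

// Brute force: enumerate every monotone warping path from (1,1) to (m,n).
// Cost-so-far pruning only discards paths that can no longer improve on the
// incumbent (costs are non-negative), so the optimum is unaffected.
static void dtw_bf_rec2(const double* x, int m, const double* y, int n,
                        int i, int j, double acc, double& best) {
  acc += std::fabs(x[i] - y[j]);
  if (acc >= best) return;
  if (i == m - 1 && j == n - 1) { best = acc; return; }
  if (i + 1 < m && j + 1 < n)
    dtw_bf_rec2(x, m, y, n, i + 1, j + 1, acc, best);
  if (i + 1 < m) dtw_bf_rec2(x, m, y, n, i + 1, j, acc, best);
  if (j + 1 < n) dtw_bf_rec2(x, m, y, n, i, j + 1, acc, best);
}

// [[Rcpp::export]]
double dtw_bruteforce_cpp(NumericVector x, NumericVector y) {
  int m = x.size(), n = y.size();
  if (m == 0 || n == 0) stop("dtw: empty series");
  double best = INF;
  dtw_bf_rec2(REAL(x), m, REAL(y), n, 0, 0, 0.0, best);
  return best;
}

// --------------------------------------------------------------- LCSS -----
// Longest common subsequence with numeric tolerance eps and warping window
// delta (|i - j| <= delta); distance = 1 - L / max(m, n).
// [[Rcpp::export]]
double lcss_cpp(NumericVector x, NumericVector y, double eps, int delta) {
  int m = x.size(), n = y.size();
  if (m == 0 || n == 0) stop("lcss: empty series");
  if (eps <= 0) stop("lcss: epsilon must be positive");
  std::vector<int> prev(n + 1, 0), cur(n + 1, 0);
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      bool match = std::fabs(x[i - 1] - y[j - 1]) <= eps &&
                   std::abs(i - j) <= delta;
      if (match) cur[j] = prev[j - 1] + 1;
      else cur[j] = std::max(prev[j], cur[j - 1]);
    }
    std::swap(prev, cur);
    std::fill(cur.begin(), cur.end(), 0);
  }
  int L = prev[n];
  return 1.0 - (double)L / (double)std::max(m, n);
}

// Backtracking check: can positions p[0..k-1] of x be matched, in order, to
// increasing positions of y obeying the eps / delta constraints?
static bool lcss_matchable(const double* x, const std::vector<int>& p, int k,
                           const double* y, int n, double eps, int delta,
                           int pi, int ystart) {
  if (pi == k) return true;
  for (int j = ystart; j < n; ++j) {
    if (std::abs(p[pi] - j) <= delta &&
        std::fabs(x[p[pi]] - y[j]) <= eps) {
      if (lcss_matchable(x, p, k, y, n, eps, delta, pi + 1, j + 1))
        return true;
    }
  }
  return false;
}

// Brute force: enumerate every subset of x's positions (as an ordered
// candidate common subsequence) and search y for a witness.
// [[Rcpp::export]]
double lcss_bruteforce_cpp(NumericVector x, NumericVector y, double eps,
                           int delta) {
  int m = x.size(), n = y.size();
  if (m == 0 || n == 0) stop("lcss: empty series");
  int bestL = 0;
  std::vector<int> p(m);
  for (unsigned s = 0; s < (1u << m); ++s) {
    int k = 0;
    for (int i = 0; i < m; ++i) if (s & (1u << i)) p[k++] = i;
    if (k <= bestL) continue;
    if (lcss_matchable(REAL(x), p, k, REAL(y), n, eps, delta, 0, 0))
      bestL = k;
  }
  return 1.0 - (double)bestL / (double)std::max(m, n);
}

// ---------------------------------------------------------------- MVM -----
// Minimal variance matching: x (the shorter series) is embedded into y by a
// strictly increasing map minimizing the summed absolute differences.
// [[Rcpp::export]]
double mvm_cpp(NumericVector x, NumericVector y) {
  int m = x.size(), n = y.size();
  if (m == 0 || n == 0) stop("mvm: empty series");
  if (m > n) stop("mvm: first series must not be longer than the second");
  // M[i][j]: best cost matching x[0..i] with x[i] -> y[j]
  std::vector<double> prev(n, INF), cur(n, INF);
  for (int j = 0; j < n; ++j) prev[j] = std::fabs(x[0] - y[j]);
  for (int i = 1; i < m; ++i) {
    double runmin = INF;
    for (int j = 0; j < n; ++j) cur[j] = INF;
    for (int j = i; j < n; ++j) {
      runmin = std::min(runmin, prev[j - 1]);
      cur[j] = std::fabs(x[i] - y[j]) + runmin;
    }
    std::swap(prev, cur);
  }
  double best = INF;
  for (int j = 0; j < n; ++j) best = std::min(best, prev[j]);
  return best;
}

static void mvm_bf_rec(const double* x, int m, const double* y, int n,
                       int i, int jprev, double acc, double& best) {
  if (i == m) { best = std::min(best, acc); return; }
  for (int j = jprev + 1; j <= n - (m - i); ++j)
    mvm_bf_rec(x, m, y, n, i + 1, j, acc + std::fabs(x[i] - y[j]), best);
}

// Brute force: enumerate all strictly increasing maps of x into y.
// [[Rcpp::export]]
double mvm_bruteforce_cpp(NumericVector x, NumericVector y) {
  int m = x.size(), n = y.size();
  if (m == 0 || n == 0) stop("mvm: empty series");
  if (m > n) stop("mvm: first series must not be longer than the second");
  double best = INF;
  mvm_bf_rec(REAL(x), m, REAL(y), n, 0, -1, 0.0, best);
  return best;
}

// -------------------------------------------------- exhaustive sweep ------
// Enumerates every pair of series with lengths 1..max_len over the supplied
// value alphabet and returns, per metric, the maximum |DP - brute force|
// discrepancy.  Used by the oracle-equivalence acceptance test; keeping the
// double loop in C++ makes the full enumeration tractable.
// [[Rcpp::export]]
List distance_oracle_sweep_cpp(NumericVector alphabet, int max_len,
                               double eps, int delta) {
  int a = alphabet.size();
  std::vector<std::vector<double>> pool;
  std::vector<int> idx;
  // enumerate all series of length 1..max_len (mixed-radix counter)
  for (int len = 1; len <= max_len; ++len) {
    idx.assign(len, 0);
    while (true) {
      std::vector<double> s(len);
      for (int i = 0; i < len; ++i) s[i] = alphabet[idx[i]];
      pool.push_back(s);
      int pos = len - 1;
      while (pos >= 0 && ++idx[pos] == a) { idx[pos] = 0; --pos; }
      if (pos < 0) break;
    }
  }
  double dd = 0, dl = 0, dm = 0;
  long long npairs = 0;
  int N = pool.size();
  for (int i = 0; i < N; ++i) {
    NumericVector xi(pool[i].begin(), pool[i].end());
    for (int j = i; j < N; ++j) {
      NumericVector yj(pool[j].begin(), pool[j].end());
      ++npairs;
      dd = std::max(dd, std::fabs(dtw_cpp(xi, yj) -
                                  dtw_bruteforce_cpp(xi, yj)));
      dl = std::max(dl, std::fabs(lcss_cpp(xi, yj, eps, delta) -
                                  lcss_bruteforce_cpp(xi, yj, eps, delta)));
      // mvm requires |x| <= |y|; pool is ordered by length
      const NumericVector& xs = (xi.size() <= yj.size()) ? xi : yj;
      const NumericVector& yl = (xi.size() <= yj.size()) ? yj : xi;
      dm = std::max(dm, std::fabs(mvm_cpp(xs, yl) -
                                  mvm_bruteforce_cpp(xs, yl)));
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["n_pairs"] = (double)npairs,
                      _["dtw_max_diff"] = dd,
                      _["lcss_max_diff"] = dl,
                      _["mvm_max_diff"] = dm);
}
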