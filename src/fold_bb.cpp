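#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cstdint>

// Exact branch-and-bound for the window-balanced fold-assignment problem:
// assign each user u (with window count P_u) to exactly one of K folds so
// that sum_k |x_k - xbar| is minimal, where x_k is the sum of window counts
// in fold k and xbar = sum(P)/K.
//
// All arithmetic is on the integer scale K*x_k - S (S = sum P), so the true
// objective is obj_scaled / K. Since sum_k (x_k - xbar) = 0, the objective
// equals 2 * sum_k max(0, x_k - xbar); fold excesses can only grow as users
// are added, giving the admissible lower bound used for pruning. Users are
// processed in decreasing P order; branches that land a user on a fold with
// the same current sum as an earlier fold are skipped (symmetric), as are
// fold choices below the fold chosen for an equal-P predecessor.

namespace {

struct BB {
  int N, K;
  long long S;
  std::vector<long long> P;     // sorted decreasing
  std::vector<int> order;       // original index of sorted position
  std::vector<long long> sums;  // K * current fold sums (actually plain sums)
  std::vector<int> assign, best_assign;
  long long best; // scaled objective: sum_k |K*x_k - S|
  long long nodes, node_cap;
  bool capped;

  long long scaled_excess() const {
    long long e = 0;
    for (int k = 0; k < K; ++k) {
      long long d = (long long)K * sums[k] - S;
      if (d > 0) e += d;
    }
    return 2 * e;
  }

  void dfs(int depth, int min_fold_for_equal) {
    if (capped) return;
    if (++nodes > node_cap) { capped = true; return; }
    if (depth == N) {
      long long obj = 0;
      for (int k = 0; k < K; ++k)
        obj += std::llabs((long long)K * sums[k] - S);
      if (obj < best) { best = obj; best_assign = assign; }
      return;
    }
    if (scaled_excess() >= best) return;  // admissible bound
    long long p = P[depth];
    // next user with equal P cannot go to an earlier fold than this one
    std::vector<long long> seen;
    seen.reserve(K);
    for (int k = 0; k < K; ++k) {
      if (k < min_fold_for_equal) continue;
      bool dup = false;
      for (long long s : seen) if (s == sums[k]) { dup = true; break; }
      if (dup) continue;
      seen.push_back(sums[k]);
      sums[k] += p;
      assign[depth] = k;
      int nxt = (depth + 1 < N && P[depth + 1] == p) ? k : 0;
      dfs(depth + 1, nxt);
      sums[k] -= p;
      if (best == 0) return;
    }
  }
};

} // namespace

// [[Rcpp::export]]
Rcpp::List fold_partition_bb(Rcpp::NumericVector P, int K,
                             double node_cap = 5e7) {
  int N = P.size();
  BB bb;
  bb.N = N; bb.K = K;
  bb.node_cap = (long long)node_cap;
  bb.nodes = 0; bb.capped = false;
  bb.P.resize(N); bb.order.resize(N);
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  std::stable_sort(idx.begin(), idx.end(),
                   [&](int a, int b) { return P[a] > P[b]; });
  bb.S = 0;
  for (int i = 0; i < N; ++i) {
    bb.order[i] = idx[i];
    bb.P[i] = (long long)P[idx[i]];
    bb.S += bb.P[i];
  }
  bb.sums.assign(K, 0);
  bb.assign.assign(N, 0);
  // LPT greedy incumbent: largest item to currently lightest fold
  {
    std::vector<long long> s(K, 0);
    std::vector<int> a(N);
    for (int i = 0; i < N; ++i) {
      int k = (int)(std::min_element(s.begin(), s.end()) - s.begin());
      s[k] += bb.P[i];
      a[i] = k;
    }
    long long obj = 0;
    for (int k = 0; k < K; ++k)
      obj += std::llabs((long long)K * s[k] - bb.S);
    bb.best = obj;
    bb.best_assign = a;
  }
  if (bb.best > 0) bb.dfs(0, 0);

  Rcpp::IntegerVector fold(N);
  std::vector<long long> x(K, 0);
  for (int i = 0; i < N; ++i) {
    fold[bb.order[i]] = bb.best_assign[i] + 1;
    x[bb.best_assign[i]] += bb.P[i];
  }
  Rcpp::NumericVector xk(K);
  for (int k = 0; k < K; ++k) xk[k] = (double)x[k];
  return Rcpp::List::create(
    Rcpp::Named("fold") = fold,
    Rcpp::Named("x") = xk,
    Rcpp::Named("objective") = (double)bb.best / K,
    Rcpp::Named("optimal") = !bb.capped,
    Rcpp::Named("nodes") = (double)bb.nodes);
}
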