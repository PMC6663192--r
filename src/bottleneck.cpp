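#include <Rcpp.h>
#include <algorithm>
#include <vector>

// Exact bottleneck value by binary search over candidate costs with a
// Kuhn augmenting-path perfect-matching feasibility check on the
// threshold graph.

static bool try_augment(int u, const std::vector<std::vector<int>> &adj,
                        std::vector<int> &matchL, std::vector<char> &seen) {
  for (int v : adj[u]) {
    if (seen[v]) continue;
    seen[v] = 1;
    if (matchL[v] < 0 || try_augment(matchL[v], adj, matchL, seen)) {
      matchL[v] = u;
      return true;
    }
  }
  return false;
}

static bool feasible(const Rcpp::NumericMatrix &cost, double cmax) {
  const int N = cost.nrow();
  std::vector<std::vector<int>> adj(N);
  for (int i = 0; i < N; ++i)
    for (int j = 0; j < N; ++j)
      if (cost(i, j) <= cmax) adj[i].push_back(j);
  std::vector<int> matchL(N, -1);
  std::vector<char> seen(N);
  for (int u = 0; u < N; ++u) {
    std::fill(seen.begin(), seen.end(), 0);
    if (!try_augment(u, adj, matchL, seen)) return false;
  }
  return true;
}

// [[Rcpp::export(name = ".bottleneck_cost_cpp")]]
double bottleneck_cost_cpp(Rcpp::NumericMatrix cost) {
  const int N = cost.nrow();
  if (N == 0) return 0.0;
  std::vector<double> cand(cost.begin(), cost.end());
  cand.push_back(0.0);
  std::sort(cand.begin(), cand.end());
  cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
  size_t lo = 0, hi = cand.size() - 1;
  while (lo < hi) {
    size_t mid = (lo + hi) / 2;
    if (feasible(cost, cand[mid] + 1e-15))
      hi = mid;
    else
      lo = mid + 1;
  }
  return cand[lo];
}
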