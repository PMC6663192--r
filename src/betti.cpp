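#include <Rcpp.h>
#include <algorithm>
#include <numeric>
#include <vector>

// Disjoint-set forest with path halving; union by size.
static int uf_find(std::vector<int> &parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

static bool uf_union(std::vector<int> &parent, std::vector<int> &size_, int a,
                     int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra == rb) return false;
  if (size_[ra] < size_[rb]) std::swap(ra, rb);
  parent[rb] = ra;
  size_[ra] += size_[rb];
  return true;
}

// Betti profile of the graph filtration of a weighted graph.
//
// Edges (ei, ej) are 0-based endpoints with weights ew (> 0; absent edges are
// simply not passed in). At filtration level eps the binary graph keeps the
// edges with weight strictly greater than eps. Inserting edges in decreasing
// weight order, the component count after the first t insertions equals
// beta0 at any eps admitting exactly those t edges; beta1 follows from the
// Euler characteristic beta1 = beta0 - p + (#edges).
//
// Returns an integer matrix with one row per query level and columns
// (beta0, beta1, nedges).
// [[Rcpp::export(name = ".betti_profile_cpp")]]
Rcpp::IntegerMatrix betti_profile_cpp(Rcpp::IntegerVector ei,
                                      Rcpp::IntegerVector ej,
                                      Rcpp::NumericVector ew, int p,
                                      Rcpp::NumericVector levels) {
  const int m = ew.size();
  std::vector<int> ord(m);
  std::iota(ord.begin(), ord.end(), 0);
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return ew[a] > ew[b]; });

  std::vector<int> parent(p), size_(p, 1);
  std::iota(parent.begin(), parent.end(), 0);

  // comp_after[t]: number of connected components once the t heaviest edges
  // are present.
  std::vector<int> comp_after(m + 1);
  comp_after[0] = p;
  int comp = p;
  for (int t = 0; t < m; ++t) {
    if (uf_union(parent, size_, ei[ord[t]], ej[ord[t]])) --comp;
    comp_after[t + 1] = comp;
  }

  std::vector<double> asc(ew.begin(), ew.end());
  std::sort(asc.begin(), asc.end());

  const int nl = levels.size();
  Rcpp::IntegerMatrix out(nl, 3);
  for (int i = 0; i < nl; ++i) {
    // edges with weight > eps
    int k = m - (int)(std::upper_bound(asc.begin(), asc.end(), levels[i]) -
                      asc.begin());
    out(i, 0) = comp_after[k];
    out(i, 1) = comp_after[k] - p + k;
    out(i, 2) = k;
  }
  return out;
}

// Persistence pairing of the graph filtration, recorded in the
// node-connecting direction (edges inserted by increasing weight).
// For each edge (ascending weight) report 1 if it merges two components
// (a dimension-0 death at that weight) or 2 if it closes a cycle (a
// dimension-1 birth at that weight).
// [[Rcpp::export(name = ".edge_roles_cpp")]]
Rcpp::IntegerVector edge_roles_cpp(Rcpp::IntegerVector ei,
                                   Rcpp::IntegerVector ej,
                                   Rcpp::NumericVector ew, int p) {
  const int m = ew.size();
  std::vector<int> ord(m);
  std::iota(ord.begin(), ord.end(), 0);
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return ew[a] < ew[b]; });

  std::vector<int> parent(p), size_(p, 1);
  std::iota(parent.begin(), parent.end(), 0);

  Rcpp::IntegerVector roles(m);
  for (int t = 0; t < m; ++t) {
    int e = ord[t];
    roles[e] = uf_union(parent, size_, ei[e], ej[e]) ? 1 : 2;
  }
  return roles;
}
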