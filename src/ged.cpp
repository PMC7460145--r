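#include <Rcpp.h>
#include <chrono>
#include <vector>
#include <algorithm>

// Typed graph edit distance by depth-first branch and bound.
//
// Unit cost model: node insertion, deletion and substitution each cost 1,
// except that substituting a node for a matching one (same type; for event
// nodes also the same activity label) is free. Edge insertions and deletions
// cost 1; an edge is preserved for free iff both endpoints are mapped and the
// corresponding edge exists in the other graph with the same direction. Node
// match classes are precomputed in R: two nodes match iff their class ids are
// equal, so node identifiers never influence the result.
//
// The search assigns g1 nodes in order to a g2 node or to deletion,
// accumulating edge costs against already-assigned nodes, with an admissible
// lower bound from the remaining class counts. It is anytime: on budget
// exhaustion the best distance found so far is returned with converged=false;
// when the search space is exhausted the result is the exact distance.

typedef std::chrono::steady_clock Clock;

struct GedSearch {
  int n1, n2;
  std::vector<int> cls1, cls2;
  std::vector<std::vector<bool>> A1, A2;
  std::vector<int> map1;      // g1 -> g2 index or -1 (deleted)
  std::vector<bool> used2;
  std::vector<int> rem1cls, rem2cls; // remaining class counts
  int ncls;
  double best;
  bool timed_out;
  long long expansions;
  Clock::time_point deadline;

  double node_bound(int depth) const {
    int n1r = n1 - depth;
    int n2r = 0;
    for (int v = 0; v < n2; ++v) if (!used2[v]) ++n2r;
    int free_pairs = 0;
    for (int c = 0; c < ncls; ++c)
      free_pairs += std::min(rem1cls[c], rem2cls[c]);
    int m = std::min(n1r, n2r);
    return n1r + n2r - m - free_pairs;
  }

  // edge cost of assigning u -> v (v == -1 for deletion), against nodes < u
  double delta_edges(int u, int v) const {
    double cost = 0.0;
    // self loop
    if (v >= 0) {
      if (A1[u][u] != A2[v][v]) cost += 1.0;
    } else if (A1[u][u]) {
      cost += 1.0;
    }
    for (int w = 0; w < u; ++w) {
      int x = map1[w];
      if (v >= 0 && x >= 0) {
        if (A1[u][w] != A2[v][x]) cost += 1.0;
        if (A1[w][u] != A2[x][v]) cost += 1.0;
      } else if (v >= 0) {            // w deleted
        if (A1[u][w]) cost += 1.0;
        if (A1[w][u]) cost += 1.0;
        // g2 edges between v and future insertions handled at completion
      } else if (x >= 0) {            // u deleted, w mapped
        if (A1[u][w]) cost += 1.0;
        if (A1[w][u]) cost += 1.0;
      } else {                        // both deleted
        if (A1[u][w]) cost += 1.0;
        if (A1[w][u]) cost += 1.0;
      }
    }
    return cost;
  }

  // cost of inserting all unused g2 nodes and their incident edges, plus g2
  // edges between mapped images whose preimage pair had no edge are already
  // counted in delta_edges; here we add edges touching >=1 unused node.
  double completion_cost() const {
    double cost = 0.0;
    for (int v = 0; v < n2; ++v) if (!used2[v]) cost += 1.0;
    for (int v = 0; v < n2; ++v)
      for (int x = 0; x < n2; ++x)
        if (A2[v][x] && (!used2[v] || !used2[x])) cost += 1.0;
    return cost;
  }

  void dfs(int depth, double g) {
    if (++expansions % 2048 == 0 && Clock::now() > deadline) {
      timed_out = true;
      return;
    }
    if (g + node_bound(depth) >= best) return;
    if (depth == n1) {
      double total = g + completion_cost();
      if (total < best) best = total;
      return;
    }
    int u = depth;
    // candidate order: matching nodes first, then mismatches, then deletion
    std::vector<std::pair<double, int>> cands;
    for (int v = 0; v < n2; ++v) {
      if (used2[v]) continue;
      double sub = (cls1[u] == cls2[v]) ? 0.0 : 1.0;
      cands.push_back({sub + delta_edges(u, v), v});
    }
    std::stable_sort(cands.begin(), cands.end(),
                     [](const std::pair<double, int>& a,
                        const std::pair<double, int>& b) {
                       return a.first < b.first;
                     });
    for (auto& c : cands) {
      int v = c.second;
      map1[u] = v;
      used2[v] = true;
      --rem1cls[cls1[u]];
      --rem2cls[cls2[v]];
      dfs(depth + 1, g + c.first);
      ++rem1cls[cls1[u]];
      ++rem2cls[cls2[v]];
      used2[v] = false;
      map1[u] = -1;
      if (timed_out) return;
    }
    // deletion branch
    double del = 1.0 + delta_edges(u, -1);
    map1[u] = -1;
    --rem1cls[cls1[u]];
    dfs(depth + 1, g + del);
    ++rem1cls[cls1[u]];
    if (timed_out) return;
  }
};

// [[Rcpp::export(name = ".ged_bnb")]]
Rcpp::List ged_bnb(Rcpp::IntegerMatrix adj1, Rcpp::IntegerMatrix adj2,
                   Rcpp::IntegerVector cls1, Rcpp::IntegerVector cls2,
                   int ncls, double budget_secs) {
  GedSearch s;
  s.n1 = adj1.nrow();
  s.n2 = adj2.nrow();
  s.ncls = ncls;
  s.cls1.assign(cls1.begin(), cls1.end());
  s.cls2.assign(cls2.begin(), cls2.end());
  s.A1.assign(s.n1, std::vector<bool>(s.n1, false));
  s.A2.assign(s.n2, std::vector<bool>(s.n2, false));
  int e1 = 0, e2 = 0;
  for (int i = 0; i < s.n1; ++i)
    for (int j = 0; j < s.n1; ++j)
      if (adj1(i, j)) { s.A1[i][j] = true; ++e1; }
  for (int i = 0; i < s.n2; ++i)
    for (int j = 0; j < s.n2; ++j)
      if (adj2(i, j)) { s.A2[i][j] = true; ++e2; }
  s.map1.assign(s.n1, -1);
  s.used2.assign(s.n2, false);
  s.rem1cls.assign(ncls, 0);
  s.rem2cls.assign(ncls, 0);
  for (int c : s.cls1) ++s.rem1cls[c];
  for (int c : s.cls2) ++s.rem2cls[c];
  // trivial upper bound: delete everything, insert everything
  s.best = s.n1 + e1 + s.n2 + e2 + 1.0;
  s.timed_out = false;
  s.expansions = 0;
  s.deadline = Clock::now() +
    std::chrono::milliseconds((long long)(budget_secs * 1000.0));

  if (s.n1 == 0) {
    s.best = s.n2 + e2;
  } else {
    double trivial = s.n1 + e1 + s.n2 + e2;
    s.best = std::min(s.best, trivial);
    s.dfs(0, 0.0);
  }
  return Rcpp::List::create(
    Rcpp::Named("distance") = s.best,
    Rcpp::Named("converged") = !s.timed_out,
    Rcpp::Named("expansions") = (double)s.expansions);
}
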