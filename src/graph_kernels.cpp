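#include <Rcpp.h>
#include <vector>
#include <queue>
#include <stack>
using namespace Rcpp;

// Adjacency lists from a symmetric 0/1 matrix (upper triangle read).
static std::vector<std::vector<int>> adj_list(const IntegerMatrix& adj) {
  int n = adj.nrow();
  std::vector<std::vector<int>> nb(n);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (adj(i, j) != 0) { nb[i].push_back(j); nb[j].push_back(i); }
  return nb;
}

// All-pairs unweighted shortest-path lengths by BFS from every source.
// Unreachable pairs are +Inf.
// [[Rcpp::export]]
NumericMatrix cpp_bfs_distances(IntegerMatrix adj) {
  int n = adj.nrow();
  std::vector<std::vector<int>> nb = adj_list(adj);
  NumericMatrix d(n, n);
  std::fill(d.begin(), d.end(), R_PosInf);
  std::vector<int> dist(n);
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    dist[s] = 0;
    std::queue<int> q;
    q.push(s);
    while (!q.empty()) {
      int u = q.front(); q.pop();
      for (int v : nb[u]) if (dist[v] < 0) { dist[v] = dist[u] + 1; q.push(v); }
    }
    for (int j = 0; j < n; ++j) if (dist[j] >= 0) d(s, j) = dist[j];
  }
  return d;
}

// Exact betweenness centrality (Brandes 2001) for an unweighted undirected
// graph, on the unordered-pair convention: each pair {h, j} contributes its
// fraction of shortest paths through i exactly once.
// [[Rcpp::export]]
NumericVector cpp_betweenness(IntegerMatrix adj) {
  int n = adj.nrow();
  std::vector<std::vector<int>> nb = adj_list(adj);
  NumericVector bc(n);
  std::vector<int> dist(n);
  std::vector<double> sigma(n), delta(n);
  std::vector<std::vector<int>> pred(n);
  for (int s = 0; s < n; ++s) {
    std::stack<int> order;
    for (int i = 0; i < n; ++i) { pred[i].clear(); dist[i] = -1; sigma[i] = 0.0; }
    dist[s] = 0; sigma[s] = 1.0;
    std::queue<int> q;
    q.push(s);
    while (!q.empty()) {
      int u = q.front(); q.pop();
      order.push(u);
      for (int v : nb[u]) {
        if (dist[v] < 0) { dist[v] = dist[u] + 1; q.push(v); }
        if (dist[v] == dist[u] + 1) { sigma[v] += sigma[u]; pred[v].push_back(u); }
      }
    }
    std::fill(delta.begin(), delta.end(), 0.0);
    while (!order.empty()) {
      int w = order.top(); order.pop();
      for (int u : pred[w]) delta[u] += sigma[u] / sigma[w] * (1.0 + delta[w]);
      if (w != s) bc[w] += delta[w];
    }
  }
  // each unordered pair was visited from both endpoints
  for (int i = 0; i < n; ++i) bc[i] /= 2.0;
  return bc;
}

// Degree-preserving randomization by repeated double-edge swaps:
// pick edges (a,b), (c,d) with four distinct endpoints, replace with
// (a,d), (c,b) unless that creates a self-loop or duplicate edge.
// Draws come from R's RNG so results are governed by set.seed().
// Returns list(adjacency, swaps_done, attempts).
// [[Rcpp::export]]
List cpp_double_edge_swap(IntegerMatrix adj, int n_swaps, int max_attempts) {
  int n = adj.nrow();
  IntegerMatrix a = clone(adj);
  std::vector<std::pair<int,int>> edges;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (a(i, j) != 0) edges.push_back(std::make_pair(i, j));
  int m = (int) edges.size();
  int done = 0, attempts = 0;
  if (m < 2) return List::create(_["adjacency"] = a, _["swaps_done"] = 0, _["attempts"] = 0);
  while (done < n_swaps && attempts < max_attempts) {
    ++attempts;
    int e1 = (int) (unif_rand() * m);
    int e2 = (int) (unif_rand() * m);
    if (e1 >= m) e1 = m - 1;
    if (e2 >= m) e2 = m - 1;
    if (e1 == e2) continue;
    int ax = edges[e1].first, b = edges[e1].second;
    int c = edges[e2].first, dd = edges[e2].second;
    // swap orientation of the second edge half the time so (a,d),(c,b)
    // covers both rewirings
    if (unif_rand() < 0.5) { int t = c; c = dd; dd = t; }
    if (ax == c || ax == dd || b == c || b == dd) continue;
    if (a(ax, dd) != 0 || a(c, b) != 0) continue;
    a(ax, b) = a(b, ax) = 0;
    a(c, dd) = a(dd, c) = 0;
    a(ax, dd) = a(dd, ax) = 1;
    a(c, b) = a(b, c) = 1;
    edges[e1] = std::make_pair(std::min(ax, dd), std::max(ax, dd));
    edges[e2] = std::make_pair(std::min(c, b), std::max(c, b));
    ++done;
  }
  return List::create(_["adjacency"] = a, _["swaps_done"] = done,
                      _["attempts"] = attempts);
}
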