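#include <Rcpp.h>
#include <vector>
#include <queue>
#include <stack>
using namespace Rcpp;

// Adjacency lists arrive 1-based from R.
static std::vector<std::vector<int>> to_adj(const List &adj) {
  int v = adj.size();
  std::vector<std::vector<int>> out(v);
  for (int i = 0; i < v; ++i) {
    IntegerVector nb = adj[i];
    out[i].reserve(nb.size());
    for (int k = 0; k < nb.size(); ++k) out[i].push_back(nb[k] - 1);
  }
  return out;
}

// All-pairs BFS distances of an unweighted graph; -1 marks unreachable.
// [[Rcpp::export(name = ".cpp_bfs_distances")]]
IntegerMatrix cpp_bfs_distances(List adj) {
  std::vector<std::vector<int>> g = to_adj(adj);
  int v = g.size();
  IntegerMatrix d(v, v);
  std::fill(d.begin(), d.end(), -1);
  std::vector<int> dist(v);
  for (int s = 0; s < v; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    dist[s] = 0;
    std::queue<int> q;
    q.push(s);
    while (!q.empty()) {
      int u = q.front(); q.pop();
      for (int w : g[u]) if (dist[w] < 0) { dist[w] = dist[u] + 1; q.push(w); }
    }
    for (int j = 0; j < v; ++j) d(s, j) = dist[j];
  }
  return d;
}

// Brandes accumulation for unweighted undirected graphs; unnormalised
// (each unordered pair contributes once).
// [[Rcpp::export(name = ".cpp_betweenness")]]
NumericVector cpp_betweenness(List adj) {
  std::vector<std::vector<int>> g = to_adj(adj);
  int v = g.size();
  NumericVector bc(v, 0.0);
  std::vector<int> dist(v), sigma(v);
  std::vector<double> delta(v);
  std::vector<std::vector<int>> pred(v);
  for (int s = 0; s < v; ++s) {
    std::stack<int> S;
    for (int i = 0; i < v; ++i) { pred[i].clear(); }
    std::fill(dist.begin(), dist.end(), -1);
    std::fill(sigma.begin(), sigma.end(), 0);
    std::fill(delta.begin(), delta.end(), 0.0);
    dist[s] = 0; sigma[s] = 1;
    std::queue<int> q;
    q.push(s);
    while (!q.empty()) {
      int u = q.front(); q.pop();
      S.push(u);
      for (int w : g[u]) {
        if (dist[w] < 0) { dist[w] = dist[u] + 1; q.push(w); }
        if (dist[w] == dist[u] + 1) { sigma[w] += sigma[u]; pred[w].push_back(u); }
      }
    }
    while (!S.empty()) {
      int w = S.top(); S.pop();
      for (int u : pred[w])
        delta[u] += (double)sigma[u] / sigma[w] * (1.0 + delta[w]);
      if (w != s) bc[w] += delta[w];
    }
  }
  for (int i = 0; i < v; ++i) bc[i] /= 2.0; // undirected: pairs counted twice
  return bc;
}

struct UF {
  std::vector<int> p, sz;
  UF(int n) : p(n), sz(n, 1) { for (int i = 0; i < n; ++i) p[i] = i; }
  int find(int x) { while (p[x] != x) { p[x] = p[p[x]]; x = p[x]; } return x; }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return;
    if (sz[a] < sz[b]) std::swap(a, b);
    p[b] = a; sz[a] += sz[b];
  }
};

// Connected components among "active" voxels over a fixed neighbour graph;
// labels 1..k (0 for inactive), ordered by first active voxel.
// [[Rcpp::export(name = ".cpp_components")]]
IntegerVector cpp_components(List adj, LogicalVector active) {
  std::vector<std::vector<int>> g = to_adj(adj);
  int v = g.size();
  UF uf(v);
  for (int i = 0; i < v; ++i) {
    if (!active[i]) continue;
    for (int w : g[i]) if (w > i && active[w]) uf.unite(i, w);
  }
  IntegerVector lab(v, 0);
  std::vector<int> remap(v, 0);
  int next = 0;
  for (int i = 0; i < v; ++i) {
    if (!active[i]) continue;
    int r = uf.find(i);
    if (remap[r] == 0) remap[r] = ++next;
    lab[i] = remap[r];
  }
  return lab;
}

// Threshold-free cluster enhancement of a non-negative map over a fixed
// neighbour graph: TFCE(v) = sum_h e(h,v)^E * h^H * dh over h = dh, 2dh, ...
// [[Rcpp::export(name = ".cpp_tfce")]]
NumericVector cpp_tfce(NumericVector values, List adj, double E, double H,
                       double dh) {
  std::vector<std::vector<int>> g = to_adj(adj);
  int v = g.size();
  NumericVector out(v, 0.0);
  double mx = 0;
  for (int i = 0; i < v; ++i) if (values[i] > mx) mx = values[i];
  if (mx <= 0 || dh <= 0) return out;
  int nsteps = (int)std::floor(mx / dh + 1e-9);
  for (int step = 1; step <= nsteps; ++step) {
    double h = step * dh;
    UF uf(v);
    std::vector<char> act(v, 0);
    for (int i = 0; i < v; ++i) act[i] = values[i] >= h;
    for (int i = 0; i < v; ++i) {
      if (!act[i]) continue;
      for (int w : g[i]) if (w > i && act[w]) uf.unite(i, w);
    }
    for (int i = 0; i < v; ++i) {
      if (!act[i]) continue;
      double e = uf.sz[uf.find(i)];
      out[i] += std::pow(e, E) * std::pow(h, H) * dh;
    }
  }
  return out;
}
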