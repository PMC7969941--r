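// Exact s-t min-cut via Dinic's blocking-flow algorithm, specialised for the
// per-slice segmentation graphs: n pixel nodes with terminal capacities plus
// symmetric neighbour arcs. Returns the source-side indicator per pixel
// (1 = liver). Capacities are non-negative reals; residuals below EPS are
// treated as saturated.
#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

static const double EPS = 1e-12;

struct Graph {
  std::vector<int> head, nxt, to;
  std::vector<double> cap;
  int n;
  explicit Graph(int nodes, size_t arcs_hint) : n(nodes) {
    head.assign(nodes, -1);
    nxt.reserve(arcs_hint); to.reserve(arcs_hint); cap.reserve(arcs_hint);
  }
  void add_arc(int u, int v, double c_uv, double c_vu) {
    nxt.push_back(head[u]); to.push_back(v); cap.push_back(c_uv);
    head[u] = (int)to.size() - 1;
    nxt.push_back(head[v]); to.push_back(u); cap.push_back(c_vu);
    head[v] = (int)to.size() - 1;
  }
};

static bool bfs_levels(const Graph& g, int s, int t, std::vector<int>& level) {
  std::fill(level.begin(), level.end(), -1);
  std::queue<int> q;
  level[s] = 0; q.push(s);
  while (!q.empty()) {
    int u = q.front(); q.pop();
    for (int e = g.head[u]; e != -1; e = g.nxt[e]) {
      int v = g.to[e];
      if (level[v] < 0 && g.cap[e] > EPS) {
        level[v] = level[u] + 1;
        q.push(v);
      }
    }
  }
  return level[t] >= 0;
}

static double dfs_push(Graph& g, int u, int t, double f,
                       std::vector<int>& level, std::vector<int>& iter) {
  if (u == t) return f;
  for (int& e = iter[u]; e != -1; e = g.nxt[e]) {
    int v = g.to[e];
    if (g.cap[e] > EPS && level[v] == level[u] + 1) {
      double d = dfs_push(g, v, t, std::min(f, g.cap[e]), level, iter);
      if (d > EPS) {
        g.cap[e] -= d;
        g.cap[e ^ 1] += d;
        return d;
      }
    }
  }
  level[u] = -1;  // dead end
  return 0.0;
}

// [[Rcpp::export(name = ".dinic_min_cut")]]
IntegerVector dinic_min_cut(int n, NumericVector src_cap, NumericVector snk_cap,
                            IntegerVector ep, IntegerVector eq,
                            NumericVector ecap) {
  const int s = n, t = n + 1;
  Graph g(n + 2, 4L * n + 4L * ep.size());
  for (int i = 0; i < n; ++i) {
    if (src_cap[i] > 0) g.add_arc(s, i, src_cap[i], 0.0);
    if (snk_cap[i] > 0) g.add_arc(i, t, snk_cap[i], 0.0);
  }
  for (R_xlen_t k = 0; k < ep.size(); ++k) {
    if (ecap[k] > 0) g.add_arc(ep[k] - 1, eq[k] - 1, ecap[k], ecap[k]);
  }
  std::vector<int> level(n + 2), iter(n + 2);
  while (bfs_levels(g, s, t, level)) {
    for (int u = 0; u < n + 2; ++u) iter[u] = g.head[u];
    while (dfs_push(g, s, t, R_PosInf, level, iter) > EPS) {}
  }
  // source side of the final residual graph
  std::vector<char> seen(n + 2, 0);
  std::queue<int> q;
  seen[s] = 1; q.push(s);
  while (!q.empty()) {
    int u = q.front(); q.pop();
    for (int e = g.head[u]; e != -1; e = g.nxt[e]) {
      int v = g.to[e];
      if (!seen[v] && g.cap[e] > EPS) { seen[v] = 1; q.push(v); }
    }
  }
  IntegerVector lab(n);
  for (int i = 0; i < n; ++i) lab[i] = seen[i] ? 1 : 0;
  return lab;
}
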