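// Exact discrete Wasserstein-1 via successive shortest augmenting paths on
// the bipartite transportation network. Masses are scaled to 2^40 integer
// units so flows are exact; Bellman-Ford handles the negative-cost residual
// arcs. Problem sizes here are tiny (supports = node degree + 1), so the
// O(k * n * m) relaxation is more than fast enough.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <cmath>
#include <limits>

using namespace Rcpp;

// [[Rcpp::export(name = ".cpp_wasserstein1")]]
double cpp_wasserstein1(NumericVector a, NumericVector b, NumericMatrix cost) {
  const int n = a.size(), m = b.size();
  const double scale = 1099511627776.0;  // 2^40
  double sa = 0, sb = 0;
  for (int i = 0; i < n; ++i) sa += a[i];
  for (int j = 0; j < m; ++j) sb += b[j];
  if (std::fabs(sa - sb) > 1e-9 * std::max(sa, 1.0))
    stop("mass mismatch between distributions");

  std::vector<int64_t> supply(n), demand(m);
  int64_t tot_a = 0, tot_b = 0;
  int ia = 0, ib = 0;
  for (int i = 0; i < n; ++i) {
    supply[i] = (int64_t) std::llround(a[i] / sa * scale);
    tot_a += supply[i];
    if (supply[i] > supply[ia]) ia = i;
  }
  for (int j = 0; j < m; ++j) {
    demand[j] = (int64_t) std::llround(b[j] / sb * scale);
    tot_b += demand[j];
    if (demand[j] > demand[ib]) ib = j;
  }
  supply[ia] += (int64_t) scale - tot_a;
  demand[ib] += (int64_t) scale - tot_b;

  std::vector<std::vector<int64_t> > flow(n, std::vector<int64_t>(m, 0));
  const double INF = std::numeric_limits<double>::infinity();

  int64_t remaining = (int64_t) scale;
  while (remaining > 0) {
    // Bellman-Ford over sources (0..n-1) and sinks (n..n+m-1)
    std::vector<double> dist(n + m, INF);
    std::vector<int> pred(n + m, -1);
    for (int i = 0; i < n; ++i) if (supply[i] > 0) dist[i] = 0.0;
    bool changed = true;
    for (int round = 0; round < n + m + 1 && changed; ++round) {
      changed = false;
      for (int i = 0; i < n; ++i) {
        if (!std::isfinite(dist[i])) continue;
        for (int j = 0; j < m; ++j) {
          double nd = dist[i] + cost(i, j);
          if (nd < dist[n + j] - 1e-12) { dist[n + j] = nd; pred[n + j] = i; changed = true; }
        }
      }
      for (int j = 0; j < m; ++j) {
        if (!std::isfinite(dist[n + j])) continue;
        for (int i = 0; i < n; ++i) {
          if (flow[i][j] <= 0) continue;
          double nd = dist[n + j] - cost(i, j);
          if (nd < dist[i] - 1e-12) { dist[i] = nd; pred[i] = n + j; changed = true; }
        }
      }
    }
    int best = -1; double bd = INF;
    for (int j = 0; j < m; ++j)
      if (demand[j] > 0 && dist[n + j] < bd) { bd = dist[n + j]; best = j; }
    if (best < 0) stop("transport network infeasible");

    // trace path, find bottleneck
    std::vector<std::pair<std::pair<int,int>,int> > arcs;  // ((i,j), dir)
    int v = n + best;
    int root = -1;
    for (int guard = 0; guard < 2 * (n + m) + 2; ++guard) {
      int u = pred[v];
      if (v >= n) arcs.push_back(std::make_pair(std::make_pair(u, v - n), +1));
      else arcs.push_back(std::make_pair(std::make_pair(v, u - n), -1));
      v = u;
      if (v < n && pred[v] == -1 && supply[v] > 0) { root = v; break; }
    }
    if (root < 0) stop("transport path trace failed");

    int64_t bott = std::min(supply[root], demand[best]);
    for (size_t k = 0; k < arcs.size(); ++k)
      if (arcs[k].second < 0)
        bott = std::min(bott, flow[arcs[k].first.first][arcs[k].first.second]);
    for (size_t k = 0; k < arcs.size(); ++k)
      flow[arcs[k].first.first][arcs[k].first.second] += arcs[k].second * bott;
    supply[root] -= bott;
    demand[best] -= bott;
    remaining -= bott;
  }

  double total = 0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j)
      if (flow[i][j] > 0) total += flow[i][j] * cost(i, j);
  return total / scale;
}
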