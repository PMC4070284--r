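// Exact solution of the bipartite transportation (earth mover's) problem by
// successive shortest augmenting paths with node potentials (Dijkstra on
// reduced costs). Dense formulation: every source-sink arc exists with the
// supplied ground cost; backward residual arcs carry the flow already sent.
// Supplies/demands are real-valued and must balance.

#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

// [[Rcpp::export]]
List transport_ssp(NumericMatrix cost, NumericVector a, NumericVector b) {
  const int m = cost.nrow();
  const int n = cost.ncol();
  if (a.size() != m || b.size() != n)
    stop("supply/demand lengths must match the cost matrix");

  double sa = 0.0, sb = 0.0;
  for (int i = 0; i < m; ++i) {
    if (a[i] < 0) stop("supplies must be non-negative");
    sa += a[i];
  }
  for (int j = 0; j < n; ++j) {
    if (b[j] < 0) stop("demands must be non-negative");
    sb += b[j];
  }
  if (sa <= 0.0) stop("total supply must be positive");
  if (std::fabs(sa - sb) > 1e-9 * std::max(1.0, std::max(sa, sb)))
    stop("total supply and demand must balance");

  const double INF = std::numeric_limits<double>::infinity();
  const double tol = 1e-12 * std::max(1.0, sa);

  std::vector<double> rem_a(a.begin(), a.end());
  std::vector<double> rem_b(b.begin(), b.end());
  std::vector<double> flow((size_t)m * n, 0.0);
  // node potentials: sources 0..m-1, sinks m..m+n-1
  std::vector<double> h(m + n, 0.0);

  std::vector<double> dist(m + n);
  std::vector<int> prev(m + n);     // predecessor node (-1 = path start)
  std::vector<char> done(m + n);

  double remaining = sa;
  while (remaining > tol) {
    // multi-source Dijkstra from all sources with remaining supply
    std::fill(dist.begin(), dist.end(), INF);
    std::fill(prev.begin(), prev.end(), -1);
    std::fill(done.begin(), done.end(), 0);
    for (int i = 0; i < m; ++i)
      if (rem_a[i] > tol) dist[i] = 0.0;

    for (int iter = 0; iter < m + n; ++iter) {
      int u = -1;
      double best = INF;
      for (int v = 0; v < m + n; ++v)
        if (!done[v] && dist[v] < best) { best = dist[v]; u = v; }
      if (u < 0) break;
      done[u] = 1;
      if (u < m) {
        // forward arcs source u -> every sink
        for (int j = 0; j < n; ++j) {
          double rc = cost(u, j) + h[u] - h[m + j];
          if (rc < 0) rc = 0; // guard tiny negative round-off
          double nd = dist[u] + rc;
          if (nd < dist[m + j] - 1e-15) {
            dist[m + j] = nd;
            prev[m + j] = u;
          }
        }
      } else {
        // backward arcs sink (u-m) -> sources with positive flow
        int j = u - m;
        for (int i = 0; i < m; ++i) {
          if (flow[(size_t)i * n + j] > tol) {
            double rc = -cost(i, j) + h[u] - h[i];
            if (rc < 0) rc = 0;
            double nd = dist[u] + rc;
            if (nd < dist[i] - 1e-15) {
              dist[i] = nd;
              prev[i] = u;
            }
          }
        }
      }
    }

    // nearest sink with unmet demand
    int t = -1;
    double bestd = INF;
    for (int j = 0; j < n; ++j)
      if (rem_b[j] > tol && dist[m + j] < bestd) {
        bestd = dist[m + j];
        t = m + j;
      }
    if (t < 0)
      stop("transport infeasible: no augmenting path (numerical breakdown)");

    // bottleneck along the path
    double delta = rem_b[t - m];
    int v = t;
    while (prev[v] != -1) {
      int u = prev[v];
      if (u < m && v >= m) {
        // forward arc: unlimited capacity
      } else {
        // backward arc sink u -> source v carries flow[v][u-m]
        double f = flow[(size_t)v * n + (u - m)];
        if (f < delta) delta = f;
      }
      v = u;
    }
    if (rem_a[v] < delta) delta = rem_a[v];
    if (delta <= 0) stop("transport solver stalled (zero augmentation)");

    // apply augmentation
    int w = t;
    while (prev[w] != -1) {
      int u = prev[w];
      if (u < m && w >= m) {
        flow[(size_t)u * n + (w - m)] += delta;
      } else {
        flow[(size_t)w * n + (u - m)] -= delta;
      }
      w = u;
    }
    rem_a[w] -= delta;
    rem_b[t - m] -= delta;
    remaining -= delta;

    // potential update (Johnson), capped at the target distance so reduced
    // costs stay non-negative for nodes beyond (or unreached by) the search
    for (int v2 = 0; v2 < m + n; ++v2)
      h[v2] += (dist[v2] < bestd) ? dist[v2] : bestd;
  }

  // collect nonzero flows and total cost
  std::vector<int> fi, fj;
  std::vector<double> fm;
  double total = 0.0;
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < n; ++j) {
      double f = flow[(size_t)i * n + j];
      if (f > tol) {
        fi.push_back(i + 1);
        fj.push_back(j + 1);
        fm.push_back(f);
        total += f * cost(i, j);
      }
    }

  return List::create(_["source"] = wrap(fi), _["target"] = wrap(fj),
                      _["mass"] = wrap(fm), _["total_cost"] = total);
}
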