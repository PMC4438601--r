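#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <queue>
#include <utility>
#include <cmath>
using namespace Rcpp;

// All-pairs shortest paths (Floyd–Warshall) on a dense distance matrix.
// `d` holds direct edge lengths (1/weight), R_PosInf where no edge, 0 on
// the diagonal. n is small (brain parcellations, <= a few hundred nodes),
// so a cache-friendly dense sweep beats per-call graph construction.
// Column-major layout: inner loop walks column j updating d(., j).
// [[Rcpp::export]]
NumericMatrix cpp_floyd_warshall(NumericMatrix d) {
  int n = d.nrow();
  NumericMatrix out(clone(d));
  double *p = out.begin();
  for (int k = 0; k < n; ++k) {
    const double *colk = p + (size_t)k * n;  // d(., k)
    for (int j = 0; j < n; ++j) {
      double dkj = p[(size_t)j * n + k];     // d(k, j)
      if (dkj == R_PosInf) continue;
      double *colj = p + (size_t)j * n;      // d(., j)
      for (int i = 0; i < n; ++i) {
        double alt = colk[i] + dkj;
        if (alt < colj[i]) colj[i] = alt;
      }
    }
  }
  return out;
}

// Degree-preserving randomization by double-edge swaps on the topology.
// Edges arrive as 1-based endpoint vectors; the swap (a-b, c-d) ->
// (a-d, c-b) is accepted only if it creates no self-loop or duplicate
// edge, so the degree sequence is preserved exactly. Uses R's RNG so the
// caller's seed governs the result.
// [[Rcpp::export]]
IntegerMatrix cpp_double_edge_swap(IntegerVector ei, IntegerVector ej,
                                   int n_nodes, int n_attempts) {
  int m = ei.size();
  std::vector<int> a(ei.begin(), ei.end());
  std::vector<int> b(ej.begin(), ej.end());
  // flat adjacency flags (1-based nodes) for O(1) duplicate detection
  std::vector<char> adj((size_t)(n_nodes + 1) * (n_nodes + 1), 0);
  size_t stride = n_nodes + 1;
  for (int e = 0; e < m; ++e) {
    adj[a[e] * stride + b[e]] = 1;
    adj[b[e] * stride + a[e]] = 1;
  }
  for (int t = 0; t < n_attempts; ++t) {
    int e1 = (int)(unif_rand() * m);
    int e2 = (int)(unif_rand() * m);
    if (e1 == e2) continue;
    int u = a[e1], v = b[e1], x = a[e2], y = b[e2];
    // randomly orient the second edge
    if (unif_rand() < 0.5) std::swap(x, y);
    // proposed new edges u-y and x-v
    if (u == y || x == v) continue;                       // self-loop
    if (adj[u * stride + y] || adj[x * stride + v]) continue;  // duplicate
    adj[u * stride + v] = adj[v * stride + u] = 0;
    adj[x * stride + y] = adj[y * stride + x] = 0;
    adj[u * stride + y] = adj[y * stride + u] = 1;
    adj[x * stride + v] = adj[v * stride + x] = 1;
    b[e1] = y; a[e2] = x; b[e2] = v;
  }
  IntegerMatrix out(m, 2);
  for (int e = 0; e < m; ++e) {
    out(e, 0) = a[e];
    out(e, 1) = b[e];
  }
  return out;
}

// All-pairs shortest paths by repeated Dijkstra over an adjacency list,
// built from a dense nonnegative weight matrix (0 = no edge). Edge
// length is 1/weight. Much faster than Floyd-Warshall on the sparse
// graphs produced by proportional thresholding.
// [[Rcpp::export]]
NumericMatrix cpp_dijkstra_all(NumericMatrix A) {
  int n = A.nrow();
  std::vector< std::vector< std::pair<int, double> > > adj(n);
  const double *p = A.begin();
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i) {
      double w = p[(size_t)j * n + i];
      if (i != j && w > 0) adj[j].push_back(std::make_pair(i, 1.0 / w));
    }
  NumericMatrix D(n, n);
  std::fill(D.begin(), D.end(), R_PosInf);
  typedef std::pair<double, int> QN;  // (dist, node)
  for (int s = 0; s < n; ++s) {
    double *ds = D.begin() + (size_t)s * n;
    std::priority_queue<QN, std::vector<QN>, std::greater<QN> > q;
    ds[s] = 0.0;
    q.push(std::make_pair(0.0, s));
    while (!q.empty()) {
      QN top = q.top(); q.pop();
      int u = top.second;
      if (top.first > ds[u]) continue;
      const std::vector< std::pair<int, double> > &nb = adj[u];
      for (size_t e = 0; e < nb.size(); ++e) {
        double alt = top.first + nb[e].second;
        if (alt < ds[nb[e].first]) {
          ds[nb[e].first] = alt;
          q.push(std::make_pair(alt, nb[e].first));
        }
      }
    }
  }
  return D;
}

// Onnela weighted clustering per node: geometric mean of triangle
// weights normalized by the network maximum, divided by k(k-1).
// [[Rcpp::export]]
NumericVector cpp_onnela_clustering(NumericMatrix A) {
  int n = A.nrow();
  const double *p = A.begin();
  double mx = 0.0;
  for (size_t t = 0; t < (size_t)n * n; ++t)
    if (p[t] > mx) mx = p[t];
  NumericVector out(n);
  if (mx <= 0) return out;
  // cube-root normalized weights, dense
  std::vector<double> cb((size_t)n * n, 0.0);
  for (size_t t = 0; t < (size_t)n * n; ++t)
    if (p[t] > 0) cb[t] = std::cbrt(p[t] / mx);
  std::vector< std::vector<int> > nbr(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (j != i && p[(size_t)j * n + i] > 0) nbr[i].push_back(j);
  for (int i = 0; i < n; ++i) {
    size_t k = nbr[i].size();
    if (k < 2) continue;
    double s = 0.0;
    for (size_t a = 0; a < k; ++a) {
      int j = nbr[i][a];
      double cij = cb[(size_t)j * n + i];
      for (size_t b = a + 1; b < k; ++b) {
        int l = nbr[i][b];
        double cjl = cb[(size_t)l * n + j];
        if (cjl > 0) s += cij * cb[(size_t)l * n + i] * cjl;
      }
    }
    out[i] = 2.0 * s / (double)(k * (k - 1));
  }
  return out;
}
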