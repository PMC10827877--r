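// Weighted graph-metric kernels.
//
// Edge weights are connection strengths (|Pearson r|); shortest-path
// computations map weight w to length 1/w, the convention of the standard
// brain-connectivity toolboxes. Floyd-Warshall is used for all-pairs
// distances: node counts here are small (<= 64) and the dense cubic scan
// beats heap-based Dijkstra at that size.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// All-pairs shortest path lengths on lengths 1/w (w > 0 edges only).
static void floyd(std::vector<double>& d, int n) {
  for (int k = 0; k < n; ++k) {
    const double* dk = &d[(size_t)k * n];
    for (int i = 0; i < n; ++i) {
      double dik = d[(size_t)i * n + k];
      if (dik == INF) continue;
      double* di = &d[(size_t)i * n];
      for (int j = 0; j < n; ++j) {
        double alt = dik + dk[j];
        if (alt < di[j]) di[j] = alt;
      }
    }
  }
}

static void lengths_from_weights(const double* w, int n, std::vector<double>& d) {
  d.assign((size_t)n * n, INF);
  for (int i = 0; i < n; ++i) {
    d[(size_t)i * n + i] = 0.0;
    for (int j = 0; j < n; ++j) {
      double wij = w[(size_t)i * n + j];
      if (i != j && wij > 0) d[(size_t)i * n + j] = 1.0 / wij;
    }
  }
}

// [[Rcpp::export(name = "cpp_distances")]]
NumericMatrix cpp_distances(NumericMatrix W) {
  int n = W.nrow();
  std::vector<double> d;
  lengths_from_weights(W.begin(), n, d);
  floyd(d, n);
  NumericMatrix out(n, n);
  std::copy(d.begin(), d.end(), out.begin());
  return out;
}

// Global efficiency of a weight matrix: mean over unordered pairs of 1/d,
// with 1/inf = 0 for disconnected pairs.
static double ge_from_dist(const std::vector<double>& d, int n) {
  if (n < 2) return 0.0;
  double s = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dij = d[(size_t)i * n + j];
      if (dij > 0 && dij != INF) s += 1.0 / dij;
    }
  return s / (n * (n - 1) / 2.0);
}

// Characteristic path length: mean distance over connected unordered
// pairs; returns NA when no pair is connected. disconnected flag set via
// pointer when any pair is unreachable.
static double ll_from_dist(const std::vector<double>& d, int n, bool* disconnected) {
  double s = 0.0;
  long cnt = 0;
  *disconnected = false;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dij = d[(size_t)i * n + j];
      if (dij == INF) { *disconnected = true; continue; }
      s += dij;
      ++cnt;
    }
  if (cnt == 0) return NA_REAL;
  return s / cnt;
}

// [[Rcpp::export(name = "cpp_local_efficiency")]]
NumericVector cpp_local_efficiency(NumericMatrix W) {
  int n = W.nrow();
  NumericVector le(n);
  std::vector<int> nb(n);
  std::vector<double> d((size_t)n * n);
  const double* w = W.begin();
  for (int i = 0; i < n; ++i) {
    int k = 0;
    for (int j = 0; j < n; ++j)
      if (j != i && w[(size_t)j * n + i] > 0) nb[k++] = j;
    if (k < 2) { le[i] = 0.0; continue; }
    // build the neighbour subgraph's length matrix directly
    for (int a = 0; a < k; ++a) {
      const double* wa = &w[(size_t)nb[a] * n];
      double* da = &d[(size_t)a * k];
      for (int b = 0; b < k; ++b) {
        double wab = wa[nb[b]];
        da[b] = (a != b && wab > 0) ? 1.0 / wab : (a == b ? 0.0 : INF);
      }
    }
    floyd(d, k);
    le[i] = ge_from_dist(d, k);
  }
  return le;
}

// Onnela weighted clustering: w normalized by max weight; per node,
// sum over neighbour pairs of cubic-root triangle intensity divided by
// k(k-1). Binary mode: triangle count over possible neighbour pairs.
// [[Rcpp::export(name = "cpp_clustering")]]
NumericVector cpp_clustering(NumericMatrix W, bool binary = false) {
  int n = W.nrow();
  NumericVector cc(n);
  double wmax = 0.0;
  for (int i = 0; i < n * n; ++i) wmax = std::max(wmax, W[i]);
  if (wmax <= 0) return cc;
  for (int i = 0; i < n; ++i) {
    std::vector<int> nb;
    for (int j = 0; j < n; ++j)
      if (j != i && W(i, j) > 0) nb.push_back(j);
    int k = (int)nb.size();
    if (k < 2) { cc[i] = 0.0; continue; }
    double s = 0.0;
    for (int a = 0; a < k; ++a)
      for (int b = a + 1; b < k; ++b) {
        double wjh = W(nb[a], nb[b]);
        if (wjh <= 0) continue;
        if (binary) s += 1.0;
        else s += std::cbrt((W(i, nb[a]) / wmax) * (W(i, nb[b]) / wmax) *
                            (wjh / wmax));
      }
    cc[i] = 2.0 * s / (k * (double)(k - 1));
  }
  return cc;
}

// Full metric bundle for one weight matrix.
// [[Rcpp::export(name = "cpp_graph_metrics")]]
List cpp_graph_metrics(NumericMatrix W, bool binary_cc = false) {
  int n = W.nrow();
  IntegerVector deg(n);
  for (int i = 0; i < n; ++i) {
    int k = 0;
    for (int j = 0; j < n; ++j)
      if (j != i && W(i, j) > 0) ++k;
    deg[i] = k;
  }
  std::vector<double> d;
  lengths_from_weights(W.begin(), n, d);
  floyd(d, n);
  bool disc = false;
  double ge = ge_from_dist(d, n);
  double ll = ll_from_dist(d, n, &disc);
  NumericVector le = cpp_local_efficiency(W);
  NumericVector cc = cpp_clustering(W, binary_cc);
  int kmin = n ? *std::min_element(deg.begin(), deg.end()) : NA_INTEGER;
  double le_mean = n ? Rcpp::mean(le) : NA_REAL;
  double cc_mean = n ? Rcpp::mean(cc) : NA_REAL;
  double cc_min = n ? Rcpp::min(cc) : NA_REAL;
  return List::create(_["degree"] = deg,
                      _["K_min"] = kmin,
                      _["GE"] = ge,
                      _["LL"] = ll,
                      _["disconnected"] = disc,
                      _["LE"] = le,
                      _["LE_mean"] = le_mean,
                      _["CC"] = cc,
                      _["CC_mean"] = cc_mean,
                      _["CC_min"] = cc_min);
}

// Lean bundle for threshold-range criteria: degree minimum, clustering
// (mean and min) and characteristic path length only -- no local
// efficiency, whose per-node subgraph scans dominate on dense graphs.
// [[Rcpp::export(name = "cpp_criterion_metrics")]]
List cpp_criterion_metrics(NumericMatrix W) {
  int n = W.nrow();
  IntegerVector deg(n);
  for (int i = 0; i < n; ++i) {
    int k = 0;
    for (int j = 0; j < n; ++j)
      if (j != i && W(i, j) > 0) ++k;
    deg[i] = k;
  }
  std::vector<double> d;
  lengths_from_weights(W.begin(), n, d);
  floyd(d, n);
  bool disc = false;
  double ll = ll_from_dist(d, n, &disc);
  NumericVector cc = cpp_clustering(W, false);
  return List::create(
    _["K_min"] = n ? *std::min_element(deg.begin(), deg.end()) : NA_INTEGER,
    _["LL"] = ll,
    _["disconnected"] = disc,
    _["CC_mean"] = n ? Rcpp::mean(cc) : NA_REAL,
    _["CC_min"] = n ? Rcpp::min(cc) : NA_REAL);
}

// Degree-preserving randomization: iterative edge swaps on the upper
// triangle ((a-b),(c-d) -> (a-d),(c-b)) followed by random reassignment
// of the original weight multiset onto the rewired edges. Uses R's RNG so
// set.seed() governs reproducibility.
// [[Rcpp::export(name = "cpp_rewire_null")]]
NumericMatrix cpp_rewire_null(NumericMatrix W, int swaps_per_edge = 10) {
  int n = W.nrow();
  std::vector<std::pair<int,int> > edges;
  std::vector<double> weights;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (W(i, j) > 0) {
        edges.push_back(std::make_pair(i, j));
        weights.push_back(W(i, j));
      }
  int m = (int)edges.size();
  NumericMatrix out(n, n);
  if (m == 0) return out;
  std::vector<signed char> adj((size_t)n * n, 0);
  for (int e = 0; e < m; ++e)
    adj[(size_t)edges[e].first * n + edges[e].second] =
      adj[(size_t)edges[e].second * n + edges[e].first] = 1;
  long attempts = (long)swaps_per_edge * m;
  for (long t = 0; t < attempts; ++t) {
    int e1 = (int)(unif_rand() * m), e2 = (int)(unif_rand() * m);
    if (e1 == e2) continue;
    int a = edges[e1].first, b = edges[e1].second;
    int c = edges[e2].first, d = edges[e2].second;
    if (unif_rand() < 0.5) std::swap(c, d);
    // propose (a-d), (c-b)
    if (a == d || c == b || a == c || b == d) continue;
    if (adj[(size_t)a * n + d] || adj[(size_t)c * n + b]) continue;
    adj[(size_t)a * n + b] = adj[(size_t)b * n + a] = 0;
    adj[(size_t)c * n + d] = adj[(size_t)d * n + c] = 0;
    adj[(size_t)a * n + d] = adj[(size_t)d * n + a] = 1;
    adj[(size_t)c * n + b] = adj[(size_t)b * n + c] = 1;
    edges[e1] = std::make_pair(std::min(a, d), std::max(a, d));
    edges[e2] = std::make_pair(std::min(c, b), std::max(c, b));
  }
  // shuffle the weight multiset onto the rewired edges (Fisher-Yates)
  for (int i = m - 1; i > 0; --i) {
    int j = (int)(unif_rand() * (i + 1));
    std::swap(weights[i], weights[j]);
  }
  for (int e = 0; e < m; ++e) {
    out(edges[e].first, edges[e].second) = weights[e];
    out(edges[e].second, edges[e].first) = weights[e];
  }
  return out;
}
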