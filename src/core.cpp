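#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Deterministic Dijkstra over a CSR graph whose vertices are indexed in
// lexicographic name order (0-based). Ties in the heap are broken by the
// smaller vertex index; a tentative distance is replaced only when the new
// one is strictly smaller. This makes the retained co-optimal path a fixed,
// seedless function of the input graph.
static void dijkstra(int n,
                     const IntegerVector& ptr,
                     const IntegerVector& adj,
                     const NumericVector& w,
                     int s,
                     std::vector<double>& dist,
                     std::vector<int>& pred,
                     std::vector<int>& depth) {
  const double INF = R_PosInf;
  std::fill(dist.begin(), dist.end(), INF);
  std::fill(pred.begin(), pred.end(), -1);
  std::fill(depth.begin(), depth.end(), -1);
  dist[s] = 0.0;
  depth[s] = 0;
  typedef std::pair<double, int> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  pq.push(QE(0.0, s));
  while (!pq.empty()) {
    QE top = pq.top();
    pq.pop();
    int u = top.second;
    if (top.first > dist[u]) continue;  // stale entry
    for (int k = ptr[u]; k < ptr[u + 1]; ++k) {
      int v = adj[k];
      double nd = dist[u] + w[k];
      if (nd < dist[v]) {
        dist[v] = nd;
        pred[v] = u;
        depth[v] = depth[u] + 1;
        pq.push(QE(nd, v));
      }
    }
  }
}

// Pass 1 of the streamed all-pairs stage: path costs only (one double per
// ordered reachable pair at >= 2 edges), never the paths themselves.
// [[Rcpp::export]]
NumericVector cpp_hap_costs(int n, IntegerVector ptr, IntegerVector adj,
                            NumericVector w) {
  std::vector<double> dist(n);
  std::vector<int> pred(n), depth(n);
  std::vector<double> out;
  for (int s = 0; s < n; ++s) {
    dijkstra(n, ptr, adj, w, s, dist, pred, depth);
    for (int t = 0; t < n; ++t) {
      if (t != s && depth[t] >= 2 && R_FINITE(dist[t])) out.push_back(dist[t]);
    }
  }
  return wrap(out);
}

// Pass 2: reconstruct only the paths whose cost is at or below `cutoff`.
// Distances are recomputed identically to pass 1, so the comparison with the
// realized cutoff (itself a pass-1 value) is exact.
// [[Rcpp::export]]
List cpp_hap_paths(int n, IntegerVector ptr, IntegerVector adj,
                   NumericVector w, double cutoff) {
  std::vector<double> dist(n);
  std::vector<int> pred(n), depth(n);
  std::vector<SEXP> paths;
  std::vector<double> costs;
  for (int s = 0; s < n; ++s) {
    dijkstra(n, ptr, adj, w, s, dist, pred, depth);
    for (int t = 0; t < n; ++t) {
      if (t == s || depth[t] < 2 || !R_FINITE(dist[t]) || dist[t] > cutoff)
        continue;
      IntegerVector path(depth[t] + 1);
      int v = t;
      for (int i = depth[t]; i >= 0; --i) {
        path[i] = v + 1;  // 1-based for R
        v = pred[v];
      }
      paths.push_back(path);
      costs.push_back(dist[t]);
    }
  }
  List lp(paths.size());
  for (size_t i = 0; i < paths.size(); ++i) lp[i] = paths[i];
  return List::create(_["paths"] = lp, _["costs"] = wrap(costs));
}

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline uint64_t fnv1a_str(uint64_t h, const char* s) {
  for (; *s; ++s) {
    h ^= (uint64_t)(uint8_t)(*s);
    h *= 0x100000001B3ULL;
  }
  return h;
}

static inline uint64_t fnv1a_u64(uint64_t h, uint64_t x) {
  for (int i = 0; i < 8; ++i) {
    h ^= (x >> (8 * i)) & 0xFFULL;
    h *= 0x100000001B3ULL;
  }
  return h;
}

// Counter-based uniform draws keyed by (seed, repetition, direction,
// condition, gene): the draw for a gene depends only on the key, never on
// the order in which genes are processed.
// [[Rcpp::export]]
NumericVector cpp_keyed_uniform(int seed, int rep, std::string direction,
                                std::string condition,
                                CharacterVector genes) {
  int ng = genes.size();
  NumericVector out(ng);
  uint64_t base = 0xCBF29CE484222325ULL;
  base = fnv1a_u64(base, (uint64_t)(int64_t)seed);
  base = fnv1a_u64(base, (uint64_t)(int64_t)rep);
  base = fnv1a_str(base, direction.c_str());
  base = fnv1a_str(base, condition.c_str());
  for (int i = 0; i < ng; ++i) {
    uint64_t h = fnv1a_str(base, CHAR(STRING_ELT(genes, i)));
    out[i] = (double)(splitmix64(h) >> 11) * (1.0 / 9007199254740992.0);
  }
  return out;
}
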