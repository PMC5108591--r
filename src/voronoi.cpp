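#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Multi-source Dijkstra over the 8-connected pixel graph restricted to a
// foreground mask: every mask pixel receives the label of the seed nearest
// by in-mask (geodesic) distance. Ties broken towards the lower label so
// the result is deterministic.
struct Node {
  double dist;
  int label;
  int idx;
};
struct NodeCmp {
  bool operator()(const Node& a, const Node& b) const {
    if (a.dist != b.dist) return a.dist > b.dist;
    return a.label > b.label;
  }
};

// [[Rcpp::export]]
IntegerMatrix geodesic_voronoi_cpp(LogicalMatrix mask, IntegerMatrix seeds) {
  const int nr = mask.nrow(), nc = mask.ncol();
  if (seeds.nrow() != nr || seeds.ncol() != nc)
    stop("mask and seeds must share dimensions");
  const double INF = R_PosInf;
  std::vector<double> dist((size_t)nr * nc, INF);
  std::vector<int> lab((size_t)nr * nc, 0);
  std::priority_queue<Node, std::vector<Node>, NodeCmp> pq;

  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int idx = j * nr + i;
      if (mask[idx] && seeds[idx] > 0) {
        dist[idx] = 0.0;
        lab[idx] = seeds[idx];
        pq.push({0.0, seeds[idx], idx});
      }
    }
  }

  const int di[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dj[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const double dw[8] = {1, 1, 1, 1, M_SQRT2, M_SQRT2, M_SQRT2, M_SQRT2};

  while (!pq.empty()) {
    Node nd = pq.top();
    pq.pop();
    int idx = nd.idx;
    if (nd.dist > dist[idx] || (nd.dist == dist[idx] && nd.label != lab[idx]))
      continue;
    int i = idx % nr, j = idx / nr;
    for (int k = 0; k < 8; ++k) {
      int ni = i + di[k], nj = j + dj[k];
      if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
      int nidx = nj * nr + ni;
      if (!mask[nidx]) continue;
      double ndist = nd.dist + dw[k];
      if (ndist < dist[nidx] ||
          (ndist == dist[nidx] && nd.label < lab[nidx])) {
        dist[nidx] = ndist;
        lab[nidx] = nd.label;
        pq.push({ndist, nd.label, nidx});
      }
    }
  }

  IntegerMatrix out(nr, nc);
  for (size_t t = 0; t < lab.size(); ++t) out[t] = lab[t];
  return out;
}
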