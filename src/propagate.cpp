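#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Multi-source Dijkstra over the 8-connected pixel grid, used for
// geodesic Voronoi propagation of seed labels through a mask.
//
// Edge cost between adjacent in-mask pixels p and q with spatial step s
// (1 for axial, sqrt(2) for diagonal):
//   s * sqrt((lambda + dI^2) / (lambda + mdi2))
// where dI = I(q) - I(p) and mdi2 is the mean squared axial intensity
// difference over in-mask neighbor pairs. With uniform intensity the
// factor is 1 and the propagation reduces to the (geodesic) nearest-seed
// partition.

struct Node {
  double dist;
  int idx;
  int label;
};

struct NodeCmp {
  bool operator()(const Node& a, const Node& b) const {
    if (a.dist != b.dist) return a.dist > b.dist;
    return a.idx > b.idx;  // deterministic tie-break
  }
};

// [[Rcpp::export]]
List cpp_propagate(NumericMatrix intensity, IntegerMatrix seeds,
                   LogicalMatrix mask, double lambda) {
  const int nr = intensity.nrow(), nc = intensity.ncol();
  const int n = nr * nc;
  if (seeds.nrow() != nr || seeds.ncol() != nc ||
      mask.nrow() != nr || mask.ncol() != nc)
    stop("intensity, seeds and mask must share dimensions");
  if (lambda <= 0) stop("lambda must be > 0");

  // mean squared axial intensity difference over in-mask pairs
  double ssq = 0.0; long npair = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) continue;
      if (i + 1 < nr && mask(i + 1, j)) {
        double d = intensity(i + 1, j) - intensity(i, j);
        ssq += d * d; ++npair;
      }
      if (j + 1 < nc && mask(i, j + 1)) {
        double d = intensity(i, j + 1) - intensity(i, j);
        ssq += d * d; ++npair;
      }
    }
  }
  const double mdi2 = npair > 0 ? ssq / npair : 0.0;

  std::vector<double> dist(n, R_PosInf);
  std::vector<int> label(n, 0);
  std::vector<bool> settled(n, false);
  std::priority_queue<Node, std::vector<Node>, NodeCmp> pq;

  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (seeds(i, j) > 0 && mask(i, j)) {
        int idx = i + j * nr;
        dist[idx] = 0.0;
        label[idx] = seeds(i, j);
        pq.push({0.0, idx, seeds(i, j)});
      }
    }
  }

  const int di[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dj[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const double sqrt2 = std::sqrt(2.0);

  while (!pq.empty()) {
    Node cur = pq.top(); pq.pop();
    if (settled[cur.idx]) continue;
    settled[cur.idx] = true;
    const int ci = cur.idx % nr, cj = cur.idx / nr;
    const double Ip = intensity(ci, cj);
    for (int k = 0; k < 8; ++k) {
      const int ni = ci + di[k], nj = cj + dj[k];
      if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
      if (!mask(ni, nj)) continue;
      const int nidx = ni + nj * nr;
      if (settled[nidx]) continue;
      const double step = (k < 4) ? 1.0 : sqrt2;
      const double dI = intensity(ni, nj) - Ip;
      const double w =
        step * std::sqrt((lambda + dI * dI) / (lambda + mdi2));
      const double nd = cur.dist + w;
      if (nd < dist[nidx]) {
        dist[nidx] = nd;
        label[nidx] = cur.label;
        pq.push({nd, nidx, cur.label});
      }
    }
  }

  IntegerMatrix out(nr, nc);
  NumericMatrix dout(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      out(i, j) = label[i + j * nr];
      dout(i, j) = dist[i + j * nr];
    }
  }
  return List::create(_["labels"] = out, _["dist"] = dout,
                      _["mdi2"] = mdi2);
}
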