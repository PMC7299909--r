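#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Quasi-Euclidean geodesic distance transform on a 2D masked grid.
// Front propagation over the 8-connected pixel graph with step costs
// sqrt((di*sy)^2 + (dj*sx)^2); equivalent to Dijkstra from the seed set.
// Pixels outside the domain (or unreachable) stay +Inf.

struct Node {
  double d;
  int idx;
  bool operator<(const Node& other) const { return d > other.d; } // min-heap
};

// [[Rcpp::export(name = ".geodesic_cpp")]]
NumericMatrix geodesic_cpp(LogicalMatrix domain, LogicalMatrix seed,
                           double sy, double sx) {
  const int nr = domain.nrow(), nc = domain.ncol();
  NumericMatrix dist(nr, nc);
  std::fill(dist.begin(), dist.end(), R_PosInf);

  std::priority_queue<Node> pq;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (seed(i, j)) {
        dist(i, j) = 0.0;
        pq.push({0.0, j * nr + i});
      }

  const int di[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dj[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  double w[8];
  for (int k = 0; k < 8; ++k)
    w[k] = std::sqrt(di[k] * di[k] * sy * sy + dj[k] * dj[k] * sx * sx);

  while (!pq.empty()) {
    Node top = pq.top();
    pq.pop();
    int i = top.idx % nr, j = top.idx / nr;
    if (top.d > dist(i, j)) continue; // stale entry
    for (int k = 0; k < 8; ++k) {
      int ni = i + di[k], nj = j + dj[k];
      if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
      if (!domain(ni, nj)) continue;
      double nd = top.d + w[k];
      if (nd < dist(ni, nj)) {
        dist(ni, nj) = nd;
        pq.push({nd, nj * nr + ni});
      }
    }
  }
  return dist;
}
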