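#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Shortest weighted 8-connected path across a masked grid.
//
// weight: per-node traversal cost multiplier (>= 0); NA marks background.
// Edge cost between neighbours u,v = euclidean step * (w[u] + w[v]) / 2.
// start/end are 1-based (x, y) grid indices lying on the mask.
//
// Returns list(cost, path) where path is an n x 2 matrix of 1-based
// (x, y) indices from start to end, or cost = -1 if unreachable.
// [[Rcpp::export(name = ".grid_geodesic")]]
List grid_geodesic(NumericMatrix weight, IntegerVector start, IntegerVector end) {
  const int nx = weight.nrow(), ny = weight.ncol();
  const long n = (long)nx * ny;
  const int sx = start[0] - 1, sy = start[1] - 1;
  const int ex = end[0] - 1, ey = end[1] - 1;
  if (sx < 0 || sx >= nx || sy < 0 || sy >= ny ||
      ex < 0 || ex >= nx || ey < 0 || ey >= ny)
    stop("endpoint outside the image");
  if (NumericMatrix::is_na(weight(sx, sy)) || NumericMatrix::is_na(weight(ex, ey)))
    stop("endpoint lies on background");

  std::vector<double> dist(n, R_PosInf);
  std::vector<long> pred(n, -1);
  typedef std::pair<double, long> Node;
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;

  const int dx[8] = {1, -1, 0, 0, 1, 1, -1, -1};
  const int dy[8] = {0, 0, 1, -1, 1, -1, 1, -1};
  const double sl[8] = {1, 1, 1, 1, M_SQRT2, M_SQRT2, M_SQRT2, M_SQRT2};

  const long s = (long)sy * nx + sx, t = (long)ey * nx + ex;
  dist[s] = 0.0;
  pq.push(Node(0.0, s));
  while (!pq.empty()) {
    Node top = pq.top(); pq.pop();
    const double d = top.first;
    const long u = top.second;
    if (d > dist[u]) continue;
    if (u == t) break;
    const int ux = (int)(u % nx), uy = (int)(u / nx);
    const double wu = weight(ux, uy);
    for (int k = 0; k < 8; ++k) {
      const int vx = ux + dx[k], vy = uy + dy[k];
      if (vx < 0 || vx >= nx || vy < 0 || vy >= ny) continue;
      const double wv = weight(vx, vy);
      if (NumericMatrix::is_na(wv)) continue;
      const long v = (long)vy * nx + vx;
      const double nd = d + sl[k] * 0.5 * (wu + wv);
      if (nd < dist[v]) {
        dist[v] = nd;
        pred[v] = u;
        pq.push(Node(nd, v));
      }
    }
  }

  if (!R_FINITE(dist[t]))
    return List::create(_["cost"] = -1.0, _["path"] = R_NilValue);

  std::vector<long> rev;
  for (long v = t; v != -1; v = pred[v]) rev.push_back(v);
  const int m = (int)rev.size();
  IntegerMatrix path(m, 2);
  for (int i = 0; i < m; ++i) {
    const long v = rev[m - 1 - i];
    path(i, 0) = (int)(v % nx) + 1;
    path(i, 1) = (int)(v / nx) + 1;
  }
  return List::create(_["cost"] = dist[t], _["path"] = path);
}
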