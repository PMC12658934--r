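#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Least-cost paths on a proportion grid.
//
// Nodes are grid cells indexed row-major: id = (r - 1) * ncol + (c - 1),
// 0-based internally, with r running over matrix rows. Neighbours are the
// 8 adjacent cells. The edge weight between neighbouring cells i and j is
//   cost = d_ij / mean(max(x_i, eps), max(x_j, eps)),
// d_ij = 1 for rook moves and sqrt(2) for diagonal moves (cell units), i.e.
// the reciprocal of a conductance given by the mean cell proportion divided
// by the centre-to-centre distance.
//
// Tie-breaking: among equal-cost routes the predecessor with the lowest
// row-major index is kept, and the priority queue pops equal-distance nodes
// in ascending index order, so shortest-path trees are bit-reproducible.

static const int DR[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

struct QItem {
  double dist;
  int node;
};
struct QCmp {
  bool operator()(const QItem& a, const QItem& b) const {
    if (a.dist != b.dist) return a.dist > b.dist;
    return a.node > b.node;
  }
};

// [[Rcpp::export]]
List dijkstra_grid(NumericMatrix x, double eps, int src, IntegerVector dst) {
  const int nr = x.nrow(), nc = x.ncol(), n = nr * nc;
  if (src < 1 || src > n) stop("source cell index out of bounds");
  const double SQ2 = std::sqrt(2.0);
  std::vector<double> dist(n, std::numeric_limits<double>::infinity());
  std::vector<int> pred(n, -1);
  std::vector<bool> done(n, false);
  // floored proportions, row-major
  std::vector<double> xf(n);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c)
      xf[r * nc + c] = std::max(x(r, c), eps);

  std::priority_queue<QItem, std::vector<QItem>, QCmp> pq;
  int s0 = src - 1;
  dist[s0] = 0.0;
  pq.push({0.0, s0});
  while (!pq.empty()) {
    QItem top = pq.top();
    pq.pop();
    int u = top.node;
    if (done[u]) continue;
    done[u] = true;
    int ur = u / nc, uc = u % nc;
    for (int k = 0; k < 8; ++k) {
      int vr = ur + DR[k], vc = uc + DC[k];
      if (vr < 0 || vr >= nr || vc < 0 || vc >= nc) continue;
      int v = vr * nc + vc;
      if (done[v]) continue;
      double d = (DR[k] != 0 && DC[k] != 0) ? SQ2 : 1.0;
      double w = d / (0.5 * (xf[u] + xf[v]));
      double nd = dist[u] + w;
      if (nd < dist[v] || (nd == dist[v] && pred[v] >= 0 && u < pred[v])) {
        dist[v] = nd;
        pred[v] = u;
        pq.push({nd, v});
      }
    }
  }

  int m = dst.size();
  List paths(m);
  NumericVector ddist(m);
  for (int i = 0; i < m; ++i) {
    int t = dst[i] - 1;
    if (t < 0 || t >= n) stop("target cell index out of bounds");
    ddist[i] = dist[t];
    std::vector<int> rev;
    for (int v = t; v != -1; v = pred[v]) rev.push_back(v + 1);
    IntegerVector p(rev.rbegin(), rev.rend());
    paths[i] = p;
  }
  return List::create(_["dist"] = ddist, _["paths"] = paths);
}

// Exhaustive minimum over all simple paths, by depth-first enumeration.
// Independent of the Dijkstra routine above; intended as a brute-force
// oracle on tiny grids only (cost is exponential in grid size).

static void dfs_enum(int u, int t, double acc, double* best,
                     std::vector<bool>& used, const std::vector<double>& xf,
                     int nr, int nc) {
  if (u == t) {
    if (acc < *best) *best = acc;
    return;
  }
  if (acc >= *best) return;  // cannot improve: all edge weights positive
  int ur = u / nc, uc = u % nc;
  const double SQ2 = std::sqrt(2.0);
  for (int k = 0; k < 8; ++k) {
    int vr = ur + DR[k], vc = uc + DC[k];
    if (vr < 0 || vr >= nr || vc < 0 || vc >= nc) continue;
    int v = vr * nc + vc;
    if (used[v]) continue;
    double d = (DR[k] != 0 && DC[k] != 0) ? SQ2 : 1.0;
    double w = d / (0.5 * (xf[u] + xf[v]));
    used[v] = true;
    dfs_enum(v, t, acc + w, best, used, xf, nr, nc);
    used[v] = false;
  }
}

// [[Rcpp::export]]
double min_path_cost_bruteforce(NumericMatrix x, double eps, int src, int dst) {
  const int nr = x.nrow(), nc = x.ncol(), n = nr * nc;
  if (n > 25) stop("brute-force enumeration is limited to grids of <= 25 cells");
  if (src < 1 || src > n || dst < 1 || dst > n) stop("cell index out of bounds");
  std::vector<double> xf(n);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c)
      xf[r * nc + c] = std::max(x(r, c), eps);
  std::vector<bool> used(n, false);
  double best = std::numeric_limits<double>::infinity();
  used[src - 1] = true;
  dfs_enum(src - 1, dst - 1, 0.0, &best, used, xf, nr, nc);
  return best;
}
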