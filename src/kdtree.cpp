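// Exact nearest-neighbour search in 3-D via a median-split k-d tree.
// Used to accelerate the correspondence step of ICP.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Node {
  int point = -1;      // index into the reference set
  int axis = 0;
  int left = -1, right = -1;
};

struct KdTree {
  const double* pts;   // column-major n x 3
  int n;
  std::vector<Node> nodes;
  int root = -1;

  double coord(int i, int ax) const { return pts[i + ax * (size_t)n]; }

  int build(std::vector<int>& idx, int lo, int hi, int depth) {
    if (lo >= hi) return -1;
    int ax = depth % 3;
    int mid = (lo + hi) / 2;
    std::nth_element(idx.begin() + lo, idx.begin() + mid, idx.begin() + hi,
                     [&](int a, int b) { return coord(a, ax) < coord(b, ax); });
    int id = (int)nodes.size();
    nodes.push_back(Node());
    nodes[id].point = idx[mid];
    nodes[id].axis = ax;
    int l = build(idx, lo, mid, depth + 1);
    int r = build(idx, mid + 1, hi, depth + 1);
    nodes[id].left = l;
    nodes[id].right = r;
    return id;
  }

  void init(const double* p, int n_) {
    pts = p; n = n_;
    nodes.reserve(n);
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    root = build(idx, 0, n, 0);
  }

  void search(int node, const double q[3], int& best, double& bestd2) const {
    if (node < 0) return;
    const Node& nd = nodes[node];
    int i = nd.point;
    double dx = coord(i, 0) - q[0];
    double dy = coord(i, 1) - q[1];
    double dz = coord(i, 2) - q[2];
    double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 < bestd2) { bestd2 = d2; best = i; }
    double diff = q[nd.axis] - coord(i, nd.axis);
    int near = diff < 0 ? nd.left : nd.right;
    int far = diff < 0 ? nd.right : nd.left;
    search(near, q, best, bestd2);
    if (diff * diff < bestd2) search(far, q, best, bestd2);
  }
};

} // namespace

// [[Rcpp::export(name = ".nn_kdtree")]]
List nn_kdtree(NumericMatrix query, NumericMatrix reference) {
  if (reference.nrow() == 0)
    stop("reference point set is empty");
  if (query.ncol() != 3 || reference.ncol() != 3)
    stop("point sets must have 3 columns");
  KdTree tree;
  tree.init(reference.begin(), reference.nrow());
  int m = query.nrow();
  IntegerVector index(m);
  NumericVector distance(m);
  for (int j = 0; j < m; ++j) {
    double q[3] = { query(j, 0), query(j, 1), query(j, 2) };
    int best = -1;
    double bestd2 = std::numeric_limits<double>::infinity();
    tree.search(tree.root, q, best, bestd2);
    index[j] = best + 1;  // 1-based for R
    distance[j] = std::sqrt(bestd2);
  }
  return List::create(_["index"] = index, _["distance"] = distance);
}
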