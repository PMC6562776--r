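// Barnes-Hut approximation of the t-SNE gradient (2-D embeddings).
//
// The repulsive term sum_j q_ij w_ij (y_i - y_j) is approximated with a
// quadtree: a cell whose extent/distance ratio is below theta is collapsed
// to its center of mass. The attractive term is computed exactly from the
// (dense) affinity matrix. theta = 0 degenerates to the exact gradient.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Node {
  double cx, cy, hw;      // cell center and half-width
  double comx, comy;      // center of mass of contained points
  int count;
  int point;              // index of the single point if singleton leaf
  bool leaf;
  int child[4];
  Node(double cx_, double cy_, double hw_)
      : cx(cx_), cy(cy_), hw(hw_), comx(0), comy(0), count(0), point(-1),
        leaf(true) {
    child[0] = child[1] = child[2] = child[3] = -1;
  }
};

class QuadTree {
 public:
  explicit QuadTree(const NumericMatrix& Y) : Y_(Y) {
    int n = Y.nrow();
    double xmin = Y(0, 0), xmax = Y(0, 0), ymin = Y(0, 1), ymax = Y(0, 1);
    for (int i = 1; i < n; ++i) {
      xmin = std::min(xmin, Y(i, 0)); xmax = std::max(xmax, Y(i, 0));
      ymin = std::min(ymin, Y(i, 1)); ymax = std::max(ymax, Y(i, 1));
    }
    double hw = std::max(xmax - xmin, ymax - ymin) / 2.0 + 1e-9;
    nodes_.reserve(4 * n + 4);
    nodes_.emplace_back((xmin + xmax) / 2.0, (ymin + ymax) / 2.0, hw);
    for (int i = 0; i < n; ++i) insert(i);
  }

  // accumulate this point's repulsive numerator and its share of the
  // normalizer Z = sum_{k != l} w_kl
  void repulsion(int i, double theta, double* fx, double* fy, double* Z) const {
    double xi = Y_(i, 0), yi = Y_(i, 1);
    std::vector<int> stack;
    stack.push_back(0);
    double th2 = theta * theta;
    while (!stack.empty()) {
      int nd = stack.back();
      stack.pop_back();
      const Node& node = nodes_[nd];
      if (node.count == 0) continue;
      double dx = xi - node.comx, dy = yi - node.comy;
      double d2 = dx * dx + dy * dy;
      double cell = 2.0 * node.hw;
      if (node.leaf || cell * cell < th2 * d2) {
        double mult = node.count;
        if (node.leaf && d2 == 0.0) mult -= 1.0;  // exclude the point itself
        if (mult <= 0.0) continue;
        double w = 1.0 / (1.0 + d2);
        *Z += mult * w;
        *fx += mult * w * w * dx;
        *fy += mult * w * w * dy;
      } else {
        for (int c = 0; c < 4; ++c)
          if (node.child[c] >= 0) stack.push_back(node.child[c]);
      }
    }
  }

 private:
  const NumericMatrix& Y_;
  std::vector<Node> nodes_;

  int quadrant(int nd, double x, double y) const {
    return (x > nodes_[nd].cx ? 1 : 0) + (y > nodes_[nd].cy ? 2 : 0);
  }

  int make_child(int nd, int q) {
    double hw = nodes_[nd].hw / 2.0;
    double cx = nodes_[nd].cx + ((q & 1) ? hw : -hw);
    double cy = nodes_[nd].cy + ((q & 2) ? hw : -hw);
    nodes_.emplace_back(cx, cy, hw);
    int id = static_cast<int>(nodes_.size()) - 1;
    nodes_[nd].child[q] = id;
    return id;
  }

  void insert(int i) {
    double x = Y_(i, 0), y = Y_(i, 1);
    int nd = 0;
    while (true) {
      Node& node = nodes_[nd];
      node.count += 1;
      node.comx += (x - node.comx) / node.count;
      node.comy += (y - node.comy) / node.count;
      if (node.leaf) {
        if (node.count == 1) { node.point = i; return; }
        int j = node.point;
        if (Y_(j, 0) == x && Y_(j, 1) == y) return;  // duplicate coordinates
        if (node.hw < 1e-12) return;  // numerically coincident: keep merged
        // subdivide and push the resident point one level down
        node.leaf = false;
        node.point = -1;
        int qj = quadrant(nd, Y_(j, 0), Y_(j, 1));
        int cj = make_child(nd, qj);
        nodes_[cj].count = 1;
        nodes_[cj].comx = Y_(j, 0);
        nodes_[cj].comy = Y_(j, 1);
        nodes_[cj].point = j;
      }
      int q = quadrant(nd, x, y);
      int c = nodes_[nd].child[q];
      if (c < 0) c = make_child(nd, q);
      nd = c;
    }
  }
};

}  // namespace

// [[Rcpp::export]]
NumericMatrix bh_gradient_cpp(NumericMatrix P, NumericMatrix Y, double theta) {
  int n = Y.nrow();
  if (Y.ncol() != 2) stop("Barnes-Hut gradient requires 2-D coordinates");
  if (P.nrow() != n || P.ncol() != n) stop("P and Y dimensions disagree");
  NumericMatrix G(n, 2);

  // exact attractive term: sum_j p_ij w_ij (y_i - y_j)
  std::vector<double> ax(n, 0.0), ay(n, 0.0);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double p = P(i, j);
      if (p == 0.0) continue;
      double dx = Y(i, 0) - Y(j, 0), dy = Y(i, 1) - Y(j, 1);
      double w = 1.0 / (1.0 + dx * dx + dy * dy);
      ax[i] += p * w * dx;
      ay[i] += p * w * dy;
    }
  }

  QuadTree tree(Y);
  std::vector<double> rx(n, 0.0), ry(n, 0.0);
  double Z = 0.0;
  for (int i = 0; i < n; ++i) tree.repulsion(i, theta, &rx[i], &ry[i], &Z);
  if (Z <= 0.0) Z = 1.0;

  for (int i = 0; i < n; ++i) {
    G(i, 0) = 4.0 * (ax[i] - rx[i] / Z);
    G(i, 1) = 4.0 * (ay[i] - ry[i] / Z);
  }
  return G;
}
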