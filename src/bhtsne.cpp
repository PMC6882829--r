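// Barnes-Hut t-SNE: quadtree repulsion, sparse attraction, and the
// adaptive gradient-descent loop with momentum, gains and exaggeration.
//
// Gradient convention: the optimiser follows the convention of the
// original and Barnes-Hut reference implementations and omits the
// factor 4 of the analytic KL gradient, i.e. it descends
//   g_i = alpha * sum_j p_ij w_ij (y_i - y_j) - (1/Z) sum_j w_ij^2 (y_i - y_j)
// so that a learning rate of n/12 means what the protocol intends.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Node {
  double cx, cy, hw;       // cell centre and half-width
  double mx, my;           // sum of member coordinates
  int count;               // number of points in cell
  int child[4];            // -1 when absent
  bool leaf;
};

class QuadTree {
 public:
  std::vector<Node> nodes;

  QuadTree(const double* x, const double* y, int n) {
    double xmin = x[0], xmax = x[0], ymin = y[0], ymax = y[0];
    for (int i = 1; i < n; ++i) {
      if (x[i] < xmin) xmin = x[i];
      if (x[i] > xmax) xmax = x[i];
      if (y[i] < ymin) ymin = y[i];
      if (y[i] > ymax) ymax = y[i];
    }
    double hw = 0.5 * std::max(xmax - xmin, ymax - ymin) + 1e-9;
    nodes.reserve(3 * n);
    nodes.push_back(make_node(0.5 * (xmin + xmax), 0.5 * (ymin + ymax), hw));
    for (int i = 0; i < n; ++i) insert(0, x[i], y[i]);
    flatten();
  }

  void insert(int id, double px, double py) {
    for (;;) {
      Node& nd = nodes[id];
      nd.mx += px; nd.my += py; nd.count += 1;
      if (nd.leaf && nd.count == 1) return;  // first point settles here
      if (nd.leaf) {
        // cells below resolvable width aggregate coincident points
        if (nd.hw < 1e-10) return;
        // split: push the resident point one level down
        double rx = (nd.mx - px) / (nd.count - 1);
        double ry = (nd.my - py) / (nd.count - 1);
        nodes[id].leaf = false;
        push_down(id, rx, ry, nodes[id].count - 1);
      }
      int q = quadrant(nodes[id], px, py);
      int ch = nodes[id].child[q];
      if (ch < 0) ch = new_child(id, q);
      id = ch;
    }
  }

  // Flattened pre-order view for cache-friendly traversal:
  // comx/comy are centres of mass, size2 the squared cell diameter,
  // skip[i] the index of the next node when subtree i is not opened.
  std::vector<double> comx, comy, size2;
  std::vector<int> cnt, skip_to;
  std::vector<bool> leaf_f;

  void flatten() {
    size_t m = nodes.size();
    comx.resize(m); comy.resize(m); size2.resize(m);
    cnt.resize(m); skip_to.resize(m); leaf_f.resize(m);
    int pos = 0;
    flatten_rec(0, pos);
    n_flat = pos;
  }

  int n_flat = 0;

  // Repulsive numerator and Z contribution for a query point.
  // Includes the self term w = 1 (caller subtracts it from z).
  void force(double px, double py, double theta2,
             double& fx, double& fy, double& z) const {
    fx = fy = z = 0.0;
    int i = 0;
    while (i < n_flat) {
      double dx = px - comx[i], dy = py - comy[i];
      double d2 = dx * dx + dy * dy;
      if (leaf_f[i] || size2[i] < theta2 * d2) {
        double w = 1.0 / (1.0 + d2);
        double cw = cnt[i] * w;
        z += cw;
        double ww = cw * w;
        fx += ww * dx;
        fy += ww * dy;
        i = skip_to[i];
      } else {
        ++i;  // open the cell: children follow in pre-order
      }
    }
  }

 private:
  static Node make_node(double cx, double cy, double hw) {
    Node nd;
    nd.cx = cx; nd.cy = cy; nd.hw = hw;
    nd.mx = 0; nd.my = 0; nd.count = 0;
    nd.child[0] = nd.child[1] = nd.child[2] = nd.child[3] = -1;
    nd.leaf = true;
    return nd;
  }
  static int quadrant(const Node& nd, double px, double py) {
    return (px >= nd.cx ? 1 : 0) + (py >= nd.cy ? 2 : 0);
  }
  int new_child(int id, int q) {
    const Node& p = nodes[id];
    double h = 0.5 * p.hw;
    double cx = p.cx + ((q & 1) ? h : -h);
    double cy = p.cy + ((q & 2) ? h : -h);
    nodes.push_back(make_node(cx, cy, h));
    nodes[id].child[q] = (int)nodes.size() - 1;
    return nodes[id].child[q];
  }
  void push_down(int id, double px, double py, int m) {
    int q = quadrant(nodes[id], px, py);
    int ch = nodes[id].child[q];
    if (ch < 0) ch = new_child(id, q);
    Node& c = nodes[ch];
    c.mx += m * px; c.my += m * py; c.count += m;
    // m > 1 only for aggregated coincident points; they stay together
  }

  void flatten_rec(int id, int& pos) {
    const Node& nd = nodes[id];
    int me = pos++;
    comx[me] = nd.mx / nd.count;
    comy[me] = nd.my / nd.count;
    double sz = 2.0 * nd.hw;
    size2[me] = sz * sz;
    cnt[me] = nd.count;
    leaf_f[me] = nd.leaf;
    if (!nd.leaf) {
      for (int q = 0; q < 4; ++q)
        if (nd.child[q] >= 0) flatten_rec(nd.child[q], pos);
    }
    skip_to[me] = pos;
  }
};

// Exact dense repulsion (reference path, O(n^2)).
void dense_repulsion(const double* x, const double* y, int n,
                     double* fx, double* fy, double& Z) {
  Z = 0.0;
  for (int i = 0; i < n; ++i) { fx[i] = 0; fy[i] = 0; }
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = x[i] - x[j], dy = y[i] - y[j];
      double w = 1.0 / (1.0 + dx * dx + dy * dy);
      double ww = w * w;
      Z += 2.0 * w;
      fx[i] += ww * dx; fy[i] += ww * dy;
      fx[j] -= ww * dx; fy[j] -= ww * dy;
    }
  }
}

// spatial (Morton) ordering of query points: consecutive queries then
// traverse similar parts of the tree, which keeps the node arrays hot
void morton_order(const double* x, const double* y, int n,
                  std::vector<int>& ord) {
  double xmin = x[0], xmax = x[0], ymin = y[0], ymax = y[0];
  for (int i = 1; i < n; ++i) {
    if (x[i] < xmin) xmin = x[i];
    if (x[i] > xmax) xmax = x[i];
    if (y[i] < ymin) ymin = y[i];
    if (y[i] > ymax) ymax = y[i];
  }
  double sx = (xmax > xmin) ? 1023.0 / (xmax - xmin) : 0.0;
  double sy = (ymax > ymin) ? 1023.0 / (ymax - ymin) : 0.0;
  std::vector<uint32_t> key(n);
  for (int i = 0; i < n; ++i) {
    uint32_t a = (uint32_t)((x[i] - xmin) * sx);
    uint32_t b = (uint32_t)((y[i] - ymin) * sy);
    uint32_t k = 0;
    for (int bit = 0; bit < 10; ++bit) {
      k |= ((a >> bit) & 1u) << (2 * bit);
      k |= ((b >> bit) & 1u) << (2 * bit + 1);
    }
    key[i] = k;
  }
  ord.resize(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&key](int a, int b) { return key[a] < key[b]; });
}

}  // namespace

// Repulsive force field and normaliser Z of a 2D layout.
// Returns the numerators sum_j w_ij^2 (y_i - y_j) and Z = sum_{k != l} w_kl.
// theta = 0 computes the exact dense sums.
// [[Rcpp::export(name = ".bh_repulsion_cpp")]]
List bh_repulsion_cpp(const NumericMatrix& Y, const double theta) {
  const int n = Y.nrow();
  std::vector<double> x(n), y(n);
  for (int i = 0; i < n; ++i) { x[i] = Y(i, 0); y[i] = Y(i, 1); }
  NumericMatrix F(n, 2);
  double Z = 0.0;
  if (theta <= 0.0) {
    std::vector<double> fx(n), fy(n);
    dense_repulsion(x.data(), y.data(), n, fx.data(), fy.data(), Z);
    for (int i = 0; i < n; ++i) { F(i, 0) = fx[i]; F(i, 1) = fy[i]; }
  } else {
    QuadTree tree(x.data(), y.data(), n);
    double t2 = theta * theta;
    for (int i = 0; i < n; ++i) {
      double fx, fy, z;
      tree.force(x[i], y[i], t2, fx, fy, z);
      F(i, 0) = fx; F(i, 1) = fy;
      Z += z - 1.0;  // remove self term w_ii = 1
    }
  }
  return List::create(_["forces"] = F, _["Z"] = Z);
}

// Full t-SNE gradient-descent loop.
// P is given in CSR form (indptr 0-based length n+1, indices 0-based, values),
// symmetric with total sum 1. Y0 is the n x 2 initial layout.
// Returns the final layout, an optional per-iteration KL trace, and the
// iteration index at which coordinates became non-finite (0 if none).
// [[Rcpp::export(name = ".tsne_optimize_cpp")]]
List tsne_optimize_cpp(const IntegerVector& indptr,
                       const IntegerVector& indices,
                       const NumericVector& values,
                       const NumericMatrix& Y0,
                       const int n_iter,
                       const double eta,
                       const double momentum_early,
                       const double momentum_late,
                       const int momentum_switch_iter,
                       const double early_exaggeration,
                       const int early_exaggeration_iter,
                       const double exaggeration,
                       const double theta,
                       const bool record_cost) {
  const int n = Y0.nrow();
  std::vector<double> x(n), y(n), ux(n, 0.0), uy(n, 0.0);
  std::vector<double> gx(n, 1.0), gy(n, 1.0);  // adaptive gains
  std::vector<double> ax(n), ay(n), rx(n), ry(n);
  for (int i = 0; i < n; ++i) { x[i] = Y0(i, 0); y[i] = Y0(i, 1); }

  NumericVector cost(record_cost ? n_iter : 0);
  double const_plogp = 0.0;
  if (record_cost)
    for (int e = 0; e < values.size(); ++e)
      if (values[e] > 0) const_plogp += values[e] * std::log(values[e]);

  int bad_iter = 0;
  for (int iter = 1; iter <= n_iter; ++iter) {
    const double alpha = (iter <= early_exaggeration_iter)
                             ? early_exaggeration : exaggeration;
    const double momentum = (iter <= momentum_switch_iter)
                                ? momentum_early : momentum_late;

    // attractive forces: sum_j p_ij w_ij (y_i - y_j) over stored neighbours
    double sum_plogw = 0.0;
    for (int i = 0; i < n; ++i) {
      double fx = 0.0, fy = 0.0;
      for (int e = indptr[i]; e < indptr[i + 1]; ++e) {
        int j = indices[e];
        double dx = x[i] - x[j], dy = y[i] - y[j];
        double w = 1.0 / (1.0 + dx * dx + dy * dy);
        double pw = values[e] * w;
        fx += pw * dx; fy += pw * dy;
        if (record_cost) sum_plogw += values[e] * std::log(w);
      }
      ax[i] = fx; ay[i] = fy;
    }

    // repulsive forces
    double Z = 0.0;
    if (theta <= 0.0) {
      dense_repulsion(x.data(), y.data(), n, rx.data(), ry.data(), Z);
    } else {
      QuadTree tree(x.data(), y.data(), n);
      double t2 = theta * theta;
      std::vector<int> qorder;
      morton_order(x.data(), y.data(), n, qorder);
      for (int k = 0; k < n; ++k) {
        int i = qorder[k];
        double fx, fy, z;
        tree.force(x[i], y[i], t2, fx, fy, z);
        rx[i] = fx; ry[i] = fy;
        Z += z - 1.0;
      }
    }
    if (Z < 1e-300) Z = 1e-300;

    if (record_cost) cost[iter - 1] = const_plogp - sum_plogw + std::log(Z);

    // gradient step with per-coordinate adaptive gains and momentum
    double mx = 0.0, my = 0.0;
    bool finite = true;
    for (int i = 0; i < n; ++i) {
      double ggx = alpha * ax[i] - rx[i] / Z;
      double ggy = alpha * ay[i] - ry[i] / Z;
      gx[i] = (ggx * ux[i] < 0.0) ? gx[i] + 0.2 : gx[i] * 0.8;
      gy[i] = (ggy * uy[i] < 0.0) ? gy[i] + 0.2 : gy[i] * 0.8;
      if (gx[i] < 0.01) gx[i] = 0.01;
      if (gy[i] < 0.01) gy[i] = 0.01;
      ux[i] = momentum * ux[i] - eta * gx[i] * ggx;
      uy[i] = momentum * uy[i] - eta * gy[i] * ggy;
      x[i] += ux[i]; y[i] += uy[i];
      if (!std::isfinite(x[i]) || !std::isfinite(y[i])) finite = false;
      mx += x[i]; my += y[i];
    }
    if (!finite) { bad_iter = iter; break; }
    mx /= n; my /= n;
    for (int i = 0; i < n; ++i) { x[i] -= mx; y[i] -= my; }

    if (iter % 50 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix Y(n, 2);
  for (int i = 0; i < n; ++i) { Y(i, 0) = x[i]; Y(i, 1) = y[i]; }
  return List::create(_["Y"] = Y, _["cost"] = cost,
                      _["diverged_at"] = bad_iter);
}
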