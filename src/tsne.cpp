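#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Quadtree for Barnes-Hut approximation of the repulsive t-SNE forces.
// Nodes store a center of mass and point count; a node is treated as a
// single summary point when (node width / distance) < theta.
struct QuadTree {
  struct Node {
    double cx, cy, hw;          // center and half-width of the cell
    double mx, my;              // center of mass
    int count;                  // points in subtree
    int point;                  // index of single point if leaf with 1 point
    int child[4];               // -1 when absent
    Node(double cx_, double cy_, double hw_)
      : cx(cx_), cy(cy_), hw(hw_), mx(0), my(0), count(0), point(-1) {
      child[0] = child[1] = child[2] = child[3] = -1;
    }
  };
  std::vector<Node> nodes;
  const double *Y;
  int n;

  QuadTree(const double *Y_, int n_) : Y(Y_), n(n_) {
    double xmin = Y[0], xmax = Y[0], ymin = Y[n], ymax = Y[n];
    for (int i = 1; i < n; ++i) {
      xmin = std::min(xmin, Y[i]); xmax = std::max(xmax, Y[i]);
      ymin = std::min(ymin, Y[n + i]); ymax = std::max(ymax, Y[n + i]);
    }
    double cx = 0.5 * (xmin + xmax), cy = 0.5 * (ymin + ymax);
    double hw = 0.5 * std::max(xmax - xmin, ymax - ymin) + 1e-5;
    nodes.reserve(4 * n);
    nodes.emplace_back(cx, cy, hw);
    for (int i = 0; i < n; ++i) insert(0, i, 0);
  }

  void insert(int node, int i, int depth) {
    double x = Y[i], y = Y[n + i];
    for (;;) {
      Node &nd = nodes[node];
      double c = (double)nd.count;
      nd.mx = (nd.mx * c + x) / (c + 1.0);
      nd.my = (nd.my * c + y) / (c + 1.0);
      nd.count += 1;
      if (nd.count == 1) { nd.point = i; return; }
      // internal node (or leaf being split): push points down
      int reinsert = -1;
      if (nd.point >= 0) { reinsert = nd.point; nd.point = -1; }
      int q = quadrant(node, x, y);
      int ch = ensure_child(node, q);
      if (reinsert >= 0 && depth < 64) {
        double rx = Y[reinsert], ry = Y[n + reinsert];
        int rq = quadrant(node, rx, ry);
        int rch = ensure_child(node, rq);
        insert_point(rch, reinsert, depth + 1);
      }
      node = ch;
      ++depth;
      if (depth >= 64) { // degenerate duplicates: park point here
        Node &leaf = nodes[node];
        double lc = (double)leaf.count;
        leaf.mx = (leaf.mx * lc + x) / (lc + 1.0);
        leaf.my = (leaf.my * lc + y) / (lc + 1.0);
        leaf.count += 1;
        return;
      }
    }
  }

  // non-looping insertion used for re-inserted points
  void insert_point(int node, int i, int depth) { insert(node, i, depth); }

  int quadrant(int node, double x, double y) const {
    const Node &nd = nodes[node];
    return (x >= nd.cx ? 1 : 0) + (y >= nd.cy ? 2 : 0);
  }

  int ensure_child(int node, int q) {
    if (nodes[node].child[q] < 0) {
      const Node nd = nodes[node];
      double hw = 0.5 * nd.hw;
      double cx = nd.cx + (q & 1 ? hw : -hw);
      double cy = nd.cy + (q & 2 ? hw : -hw);
      nodes.emplace_back(cx, cy, hw);
      nodes[node].child[q] = (int)nodes.size() - 1;
    }
    return nodes[node].child[q];
  }

  // Accumulate repulsive force numerator for point i and return its
  // contribution to the normalisation constant Z.
  double repulsion(int i, double theta2, double *fx, double *fy) const {
    double x = Y[i], y = Y[n + i], z = 0.0;
    std::vector<int> stack;
    stack.reserve(128);
    stack.push_back(0);
    while (!stack.empty()) {
      int id = stack.back(); stack.pop_back();
      const Node &nd = nodes[id];
      if (nd.count == 0) continue;
      double dx = x - nd.mx, dy = y - nd.my;
      double d2 = dx * dx + dy * dy;
      bool is_summary = (4.0 * nd.hw * nd.hw) < theta2 * d2;
      bool is_leaf = nd.child[0] < 0 && nd.child[1] < 0 &&
                     nd.child[2] < 0 && nd.child[3] < 0;
      if (is_summary || is_leaf) {
        if (is_leaf && nd.point == i) continue; // skip the self leaf
        double cnt = (double)nd.count;
        double q = 1.0 / (1.0 + d2);
        z += cnt * q;
        double q2 = cnt * q * q;
        *fx += q2 * dx;
        *fy += q2 * dy;
      } else {
        for (int k = 0; k < 4; ++k)
          if (nd.child[k] >= 0) stack.push_back(nd.child[k]);
      }
    }
    return z;
  }
};

// Run the t-SNE gradient descent.
// P: symmetric joint affinities (n x n, sums to 1). Y0: n x 2 init.
// Returns final coordinates and the KL trace (on the unexaggerated P)
// recorded every record_every iterations and at the final iteration.
// theta == 0 selects the exact O(n^2) gradient; theta > 0 approximates
// the repulsive term with a Barnes-Hut quadtree.
// [[Rcpp::export]]
List tsne_gradient_cpp(NumericMatrix P, NumericMatrix Y0, int iterations,
                       double theta, double learning_rate,
                       double early_exaggeration, int exaggeration_iter,
                       double momentum, double final_momentum,
                       int momentum_switch, int record_every) {
  const int n = Y0.nrow();
  if (P.nrow() != n || P.ncol() != n)
    stop("P must be n x n matching Y0 rows");
  std::vector<double> Y(Y0.begin(), Y0.end());
  std::vector<double> inc(2 * n, 0.0), gains(2 * n, 1.0), grad(2 * n, 0.0);
  std::vector<double> attr(2 * n), rep(2 * n);
  std::vector<int> trace_iter;
  std::vector<double> trace_kl;
  const double theta2 = theta * theta;
  const double *p = P.begin();

  for (int iter = 1; iter <= iterations; ++iter) {
    double ex = (iter <= exaggeration_iter) ? early_exaggeration : 1.0;
    double Z = 0.0;
    std::fill(attr.begin(), attr.end(), 0.0);
    std::fill(rep.begin(), rep.end(), 0.0);
    double plogq_num = 0.0; // sum_ij p_ij * log(q*_ij)  (q* = 1/(1+d2))

    if (theta <= 0.0) {
      for (int i = 0; i < n; ++i) {
        double xi = Y[i], yi = Y[n + i];
        double ax = 0.0, ay = 0.0, rx = 0.0, ry = 0.0;
        for (int j = 0; j < n; ++j) {
          if (j == i) continue;
          double dx = xi - Y[j], dy = yi - Y[n + j];
          double q = 1.0 / (1.0 + dx * dx + dy * dy);
          double pij = p[i + (size_t)n * j];
          ax += pij * q * dx;
          ay += pij * q * dy;
          rx += q * q * dx;
          ry += q * q * dy;
          Z += q;
          if (pij > 0) plogq_num += pij * std::log(q);
        }
        attr[i] = ax; attr[n + i] = ay;
        rep[i] = rx; rep[n + i] = ry;
      }
    } else {
      QuadTree tree(Y.data(), n);
      for (int i = 0; i < n; ++i) {
        double rx = 0.0, ry = 0.0;
        Z += tree.repulsion(i, theta2, &rx, &ry);
        rep[i] = rx; rep[n + i] = ry;
      }
      // attractive term stays dense: P is dense and small at this scale
      for (int i = 0; i < n; ++i) {
        double xi = Y[i], yi = Y[n + i];
        double ax = 0.0, ay = 0.0;
        for (int j = 0; j < n; ++j) {
          double pij = p[i + (size_t)n * j];
          if (pij <= 0.0 || j == i) continue;
          double dx = xi - Y[j], dy = yi - Y[n + j];
          double q = 1.0 / (1.0 + dx * dx + dy * dy);
          ax += pij * q * dx;
          ay += pij * q * dy;
          plogq_num += pij * std::log(q);
        }
        attr[i] = ax; attr[n + i] = ay;
      }
    }
    if (Z < 1e-300) Z = 1e-300;

    for (int k = 0; k < 2 * n; ++k) {
      grad[k] = 4.0 * (ex * attr[k] - rep[k] / Z);
      if (!std::isfinite(grad[k]))
        stop("non-finite t-SNE gradient at iteration %d", iter);
    }

    double mom = (iter <= momentum_switch) ? momentum : final_momentum;
    for (int k = 0; k < 2 * n; ++k) {
      double g = grad[k];
      gains[k] = ((g > 0) != (inc[k] > 0)) ? gains[k] + 0.2 : gains[k] * 0.8;
      if (gains[k] < 0.01) gains[k] = 0.01;
      inc[k] = mom * inc[k] - learning_rate * gains[k] * g;
      Y[k] += inc[k];
    }
    // recentre to remove the translational degree of freedom
    double mx = 0.0, my = 0.0;
    for (int i = 0; i < n; ++i) { mx += Y[i]; my += Y[n + i]; }
    mx /= n; my /= n;
    for (int i = 0; i < n; ++i) { Y[i] -= mx; Y[n + i] -= my; }

    if (iter % record_every == 0 || iter == iterations) {
      // KL(P||Q) with Q from this iteration's Z (pre-update geometry):
      // sum p log p - sum p log q*, plus log Z  (since q = q*/Z)
      double plogp = 0.0;
      for (size_t k = 0; k < (size_t)n * n; ++k)
        if (p[k] > 0) plogp += p[k] * std::log(p[k]);
      double kl = plogp - plogq_num + std::log(Z);
      trace_iter.push_back(iter);
      trace_kl.push_back(kl);
    }
  }

  NumericMatrix Yout(n, 2);
  std::copy(Y.begin(), Y.end(), Yout.begin());
  return List::create(_["Y"] = Yout,
                      _["trace_iteration"] = wrap(trace_iter),
                      _["trace_kl"] = wrap(trace_kl));
}
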