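#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Regression trees are flat numeric matrices, one row per node, columns
// (feature, threshold, left, right, value, cover). `feature`, `left`,
// `right` are 1-based; leaves carry feature = -1 and left = right = -1.
// Routing convention everywhere: x[feature] <= threshold goes LEFT.

static inline bool is_leaf(const NumericMatrix &tree, int node) {
  return tree(node, 0) < 0;
}

static inline int route_child(const NumericMatrix &tree, int node, const double *x) {
  int f = (int)tree(node, 0) - 1;
  double thr = tree(node, 1);
  return (x[f] <= thr) ? (int)tree(node, 2) - 1 : (int)tree(node, 3) - 1;
}

// ---------------------------------------------------------------- building

struct BuildNode {
  int feature;      // 1-based, -1 leaf
  double threshold;
  int left, right;  // 0-based ids during build, -1 leaf
  double value;
  double cover;
};

struct Builder {
  const NumericMatrix &X;
  const NumericVector &g, &h;
  int max_depth;
  double lambda, colsample;
  int min_child;
  std::vector<BuildNode> nodes;

  Builder(const NumericMatrix &X_, const NumericVector &g_, const NumericVector &h_,
          int md, double lam, double cs, int mc)
    : X(X_), g(g_), h(h_), max_depth(md), lambda(lam), colsample(cs), min_child(mc) {}

  int make_leaf(double G, double H, double cover) {
    BuildNode nd;
    nd.feature = -1; nd.threshold = NA_REAL; nd.left = -1; nd.right = -1;
    nd.value = -G / (H + lambda);
    nd.cover = cover;
    nodes.push_back(nd);
    return (int)nodes.size() - 1;
  }

  int build(std::vector<int> &rows, int depth) {
    int nr = (int)rows.size();
    double G = 0.0, H = 0.0;
    for (int i = 0; i < nr; ++i) { G += g[rows[i]]; H += h[rows[i]]; }
    if (depth >= max_depth || nr < 2 * min_child)
      return make_leaf(G, H, nr);

    int n = X.ncol();
    IntegerVector cand;
    if (colsample < 1.0) {
      int k = std::max(1, (int)std::floor(colsample * n));
      cand = Rcpp::sample(n, k, false); // 1-based, uses R's RNG
    } else {
      cand = IntegerVector(n);
      for (int j = 0; j < n; ++j) cand[j] = j + 1;
    }

    double parent_score = G * G / (H + lambda);
    double best_gain = 0.0, best_thr = 0.0;
    int best_feat = -1;

    std::vector<std::pair<double, int> > vals(nr);
    for (int ci = 0; ci < cand.size(); ++ci) {
      int f = cand[ci] - 1;
      for (int i = 0; i < nr; ++i) vals[i] = std::make_pair(X(rows[i], f), rows[i]);
      std::sort(vals.begin(), vals.end());
      double GL = 0.0, HL = 0.0;
      for (int i = 0; i < nr - 1; ++i) {
        GL += g[vals[i].second]; HL += h[vals[i].second];
        if (vals[i].first == vals[i + 1].first) continue;
        int nl = i + 1, nrr = nr - nl;
        if (nl < min_child || nrr < min_child) continue;
        double GR = G - GL, HR = H - HL;
        double gain = 0.5 * (GL * GL / (HL + lambda) + GR * GR / (HR + lambda) - parent_score);
        if (gain > best_gain + 1e-12) {
          best_gain = gain;
          best_feat = f;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }

    if (best_feat < 0 || best_gain <= 1e-12)
      return make_leaf(G, H, nr);

    std::vector<int> lrows, rrows;
    lrows.reserve(nr); rrows.reserve(nr);
    for (int i = 0; i < nr; ++i) {
      if (X(rows[i], best_feat) <= best_thr) lrows.push_back(rows[i]);
      else rrows.push_back(rows[i]);
    }
    // guard against degenerate partitions from midpoint rounding
    if (lrows.empty() || rrows.empty())
      return make_leaf(G, H, nr);

    BuildNode nd;
    nd.feature = best_feat + 1; nd.threshold = best_thr;
    nd.value = NA_REAL; nd.cover = nr;
    nodes.push_back(nd);
    int id = (int)nodes.size() - 1;
    int lid = build(lrows, depth + 1);
    int rid = build(rrows, depth + 1);
    nodes[id].left = lid; nodes[id].right = rid;
    return id;
  }
};

// [[Rcpp::export]]
NumericMatrix cpp_build_tree(NumericMatrix X, NumericVector g, NumericVector h,
                             IntegerVector rows, int max_depth, double lambda,
                             double colsample, int min_child) {
  Builder b(X, g, h, max_depth, lambda, colsample, min_child);
  std::vector<int> r(rows.begin(), rows.end()); // 0-based row indices
  b.build(r, 0);
  int nn = (int)b.nodes.size();
  NumericMatrix out(nn, 6);
  for (int i = 0; i < nn; ++i) {
    const BuildNode &nd = b.nodes[i];
    out(i, 0) = nd.feature;
    out(i, 1) = nd.threshold;
    out(i, 2) = nd.left < 0 ? -1 : nd.left + 1;
    out(i, 3) = nd.right < 0 ? -1 : nd.right + 1;
    out(i, 4) = nd.value;
    out(i, 5) = nd.cover;
  }
  colnames(out) = CharacterVector::create("feature", "threshold", "left",
                                          "right", "value", "cover");
  return out;
}

// Count of X rows routed through every node (root included).
// [[Rcpp::export]]
NumericVector cpp_tree_covers(NumericMatrix tree, NumericMatrix X) {
  int m = X.nrow(), n = X.ncol();
  NumericVector cover(tree.nrow());
  std::vector<double> x(n);
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < n; ++j) x[j] = X(i, j);
    int node = 0;
    cover[node] += 1.0;
    while (!is_leaf(tree, node)) {
      node = route_child(tree, node, x.data());
      cover[node] += 1.0;
    }
  }
  return cover;
}

// [[Rcpp::export]]
NumericVector cpp_tree_predict(NumericMatrix tree, NumericMatrix X) {
  int m = X.nrow(), n = X.ncol();
  NumericVector out(m);
  std::vector<double> x(n);
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < n; ++j) x[j] = X(i, j);
    int node = 0;
    while (!is_leaf(tree, node)) node = route_child(tree, node, x.data());
    out[i] = tree(node, 4);
  }
  return out;
}

// Sum over trees of tau_k(x_i) (unscaled by the learning rate).
// [[Rcpp::export]]
NumericVector cpp_ensemble_predict(List trees, NumericMatrix X) {
  int m = X.nrow();
  NumericVector out(m);
  for (int k = 0; k < trees.size(); ++k) {
    NumericMatrix tr = trees[k];
    NumericVector p = cpp_tree_predict(tr, X);
    for (int i = 0; i < m; ++i) out[i] += p[i];
  }
  return out;
}

// Cover-weighted mean of leaf values: the tree-path-dependent E[tau(x)]
// conditioned on the empty coalition.
// [[Rcpp::export]]
double cpp_tree_mean(NumericMatrix tree) {
  int nn = tree.nrow();
  double tot = 0.0, wsum = 0.0;
  for (int i = 0; i < nn; ++i) {
    if (tree(i, 0) < 0) { tot += tree(i, 5) * tree(i, 4); wsum += tree(i, 5); }
  }
  if (wsum <= 0) stop("tree has zero total leaf cover");
  return tot / wsum;
}

// --------------------------------------------------- path-dependent TreeSHAP
// Maintains, per root-to-node path, the proportion of feature subsets of each
// cardinality that flow down the path, split into 'one' (feature matches x)
// and 'zero' (cover-fraction) weights; EXTEND/UNWIND recurrences as in the
// polynomial-time tree explainer.

struct PathElement {
  int d;        // feature index (0-based), -1 for the root placeholder
  double z;     // zero fraction (cover proportion)
  double o;     // one fraction (0/1 routing indicator)
  double w;     // subset proportion weight
};

static void ts_extend(std::vector<PathElement> &path, double pz, double po, int pi) {
  int l = (int)path.size();
  PathElement el; el.d = pi; el.z = pz; el.o = po; el.w = (l == 0 ? 1.0 : 0.0);
  path.push_back(el);
  for (int i = l - 1; i >= 0; --i) {
    path[i + 1].w += po * path[i].w * (i + 1) / (double)(l + 1);
    path[i].w = pz * path[i].w * (l - i) / (double)(l + 1);
  }
}

static void ts_unwind(std::vector<PathElement> &path, int index) {
  int l = (int)path.size() - 1;
  double o = path[index].o, z = path[index].z;
  double next_one = path[l].w;
  for (int i = l - 1; i >= 0; --i) {
    if (o != 0.0) {
      double tmp = path[i].w;
      path[i].w = next_one * (l + 1) / (double)((i + 1) * o);
      next_one = tmp - path[i].w * z * (l - i) / (double)(l + 1);
    } else {
      path[i].w = path[i].w * (l + 1) / (double)(z * (l - i));
    }
  }
  for (int i = index; i < l; ++i) {
    path[i].d = path[i + 1].d;
    path[i].z = path[i + 1].z;
    path[i].o = path[i + 1].o;
  }
  path.pop_back();
}

static double ts_unwound_sum(const std::vector<PathElement> &path, int index) {
  int l = (int)path.size() - 1;
  double o = path[index].o, z = path[index].z;
  double total = 0.0;
  double next_one = path[l].w;
  for (int i = l - 1; i >= 0; --i) {
    if (o != 0.0) {
      double tmp = next_one * (l + 1) / (double)((i + 1) * o);
      total += tmp;
      next_one = path[i].w - tmp * z * (l - i) / (double)(l + 1);
    } else {
      total += path[i].w * (l + 1) / (double)(z * (l - i));
    }
  }
  return total;
}

static void ts_recurse(const NumericMatrix &tree, const double *x, double *phi,
                       int node, std::vector<PathElement> path,
                       double pz, double po, int pi) {
  ts_extend(path, pz, po, pi);
  if (is_leaf(tree, node)) {
    double v = tree(node, 4);
    int l = (int)path.size() - 1;
    for (int i = 1; i <= l; ++i) {
      double w = ts_unwound_sum(path, i);
      phi[path[i].d] += w * (path[i].o - path[i].z) * v;
    }
    return;
  }
  int f = (int)tree(node, 0) - 1;
  double thr = tree(node, 1);
  int left = (int)tree(node, 2) - 1, right = (int)tree(node, 3) - 1;
  int hot = (x[f] <= thr) ? left : right;
  int cold = (hot == left) ? right : left;
  double cover_node = tree(node, 5);
  if (cover_node <= 0) stop("zero cover at an internal node");
  double iz = 1.0, io = 1.0;
  int k = -1;
  for (int i = 1; i < (int)path.size(); ++i)
    if (path[i].d == f) { k = i; break; }
  if (k >= 0) {
    iz = path[k].z; io = path[k].o;
    ts_unwind(path, k);
  }
  ts_recurse(tree, x, phi, hot, path,
             tree(hot, 5) / cover_node * iz, io, f);
  ts_recurse(tree, x, phi, cold, path,
             tree(cold, 5) / cover_node * iz, 0.0, f);
}

// [[Rcpp::export]]
NumericMatrix cpp_tree_shapley(NumericMatrix tree, NumericMatrix X) {
  int m = X.nrow(), n = X.ncol();
  NumericMatrix phi(m, n);
  std::vector<double> x(n);
  std::vector<double> acc(n);
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < n; ++j) { x[j] = X(i, j); acc[j] = 0.0; }
    std::vector<PathElement> path;
    path.reserve(16);
    ts_recurse(tree, x.data(), acc.data(), 0, path, 1.0, 1.0, -1);
    for (int j = 0; j < n; ++j) phi(i, j) = acc[j];
  }
  return phi;
}

// Accumulated, unscaled Shapley values over an ensemble's trees.
// [[Rcpp::export]]
NumericMatrix cpp_ensemble_shapley(List trees, NumericMatrix X) {
  int m = X.nrow(), n = X.ncol();
  NumericMatrix phi(m, n);
  for (int k = 0; k < trees.size(); ++k) {
    NumericMatrix tr = trees[k];
    NumericMatrix pk = cpp_tree_shapley(tr, X);
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < m; ++i)
        phi(i, j) += pk(i, j);
    Rcpp::checkUserInterrupt();
  }
  return phi;
}
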