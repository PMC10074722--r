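// Gradient-boosted decision trees for binary classification.
//
// Second-order (Newton) boosting on the logistic loss, with leaf-wise
// best-first tree growth capped by num_leaves and max_depth — the growth
// strategy popularised by histogram GBDT frameworks. Split search is exact
// greedy over globally presorted feature orders with node-membership flags,
// so no per-node sorting is needed. Fully deterministic: no row or feature
// subsampling.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

const double kEps = 1e-12;

struct SplitInfo {
  double gain = -1.0;
  int feature = -1;
  double threshold = 0.0;
};

struct Node {
  std::vector<int> rows;
  int depth = 0;
  double G = 0.0, H = 0.0;
  SplitInfo split;
  int id = -1; // index into the output node table
};

// Column-major copy of the training matrix plus per-feature sorted row order.
struct TrainData {
  int n = 0, p = 0;
  std::vector<double> x;      // column-major, n * p
  std::vector<int> order;     // per feature, rows sorted by value (stable)
  double at(int i, int j) const { return x[static_cast<size_t>(j) * n + i]; }
};

double split_score(double G, double H) { return G * G / (H + kEps); }

SplitInfo best_split(const TrainData& td, const std::vector<double>& g,
                     const std::vector<double>& h,
                     const Node& node, std::vector<char>& in_node,
                     int min_data) {
  SplitInfo best;
  const int n = node.rows.size();
  if (n < 2 * min_data) return best;
  const double parent = split_score(node.G, node.H);
  for (int r : node.rows) in_node[r] = 1;

  for (int j = 0; j < td.p; ++j) {
    const int* ord = &td.order[static_cast<size_t>(j) * td.n];
    double GL = 0.0, HL = 0.0, prev_val = 0.0;
    int cnt = 0;
    for (int k = 0; k < td.n; ++k) {
      const int r = ord[k];
      if (!in_node[r]) continue;
      const double v = td.at(r, j);
      if (cnt > 0 && v != prev_val && cnt >= min_data && n - cnt >= min_data) {
        const double gain = split_score(GL, HL) +
                            split_score(node.G - GL, node.H - HL) - parent;
        if (gain > best.gain + kEps) {
          best.gain = gain;
          best.feature = j;
          best.threshold = 0.5 * (prev_val + v);
        }
      }
      GL += g[r];
      HL += h[r];
      prev_val = v;
      ++cnt;
    }
  }
  for (int r : node.rows) in_node[r] = 0;
  if (best.gain <= 0.0) best.feature = -1;
  return best;
}

void push_leaf(std::vector<int>& feature, std::vector<double>& threshold,
               std::vector<int>& left, std::vector<int>& right,
               std::vector<double>& value, double leaf_value) {
  feature.push_back(-1);
  threshold.push_back(0.0);
  left.push_back(-1);
  right.push_back(-1);
  value.push_back(leaf_value);
}

void grow_tree(const TrainData& td, const std::vector<double>& g,
               const std::vector<double>& h, int max_depth, int num_leaves,
               int min_data, double learning_rate, std::vector<char>& in_node,
               std::vector<int>& feature, std::vector<double>& threshold,
               std::vector<int>& left, std::vector<int>& right,
               std::vector<double>& value) {
  std::vector<Node> leaves;

  Node root;
  root.rows.resize(td.n);
  for (int i = 0; i < td.n; ++i) root.rows[i] = i;
  for (int r : root.rows) { root.G += g[r]; root.H += h[r]; }
  root.split = best_split(td, g, h, root, in_node, min_data);
  root.id = 0;
  push_leaf(feature, threshold, left, right, value,
            learning_rate * (-root.G / (root.H + kEps)));
  leaves.push_back(std::move(root));

  int n_leaves = 1;
  while (n_leaves < num_leaves) {
    int pick = -1;
    double best_gain = 0.0;
    for (size_t i = 0; i < leaves.size(); ++i) {
      if (leaves[i].depth >= max_depth || leaves[i].split.feature < 0) continue;
      if (leaves[i].split.gain > best_gain + kEps) {
        best_gain = leaves[i].split.gain;
        pick = static_cast<int>(i);
      }
    }
    if (pick < 0) break;

    Node parent = std::move(leaves[pick]);
    leaves.erase(leaves.begin() + pick);

    Node lchild, rchild;
    lchild.depth = rchild.depth = parent.depth + 1;
    for (int r : parent.rows) {
      if (td.at(r, parent.split.feature) <= parent.split.threshold) {
        lchild.rows.push_back(r);
        lchild.G += g[r];
        lchild.H += h[r];
      } else {
        rchild.rows.push_back(r);
        rchild.G += g[r];
        rchild.H += h[r];
      }
    }
    lchild.split = best_split(td, g, h, lchild, in_node, min_data);
    rchild.split = best_split(td, g, h, rchild, in_node, min_data);

    // the picked leaf becomes an internal node
    feature[parent.id] = parent.split.feature;
    threshold[parent.id] = parent.split.threshold;
    lchild.id = static_cast<int>(feature.size());
    push_leaf(feature, threshold, left, right, value,
              learning_rate * (-lchild.G / (lchild.H + kEps)));
    rchild.id = static_cast<int>(feature.size());
    push_leaf(feature, threshold, left, right, value,
              learning_rate * (-rchild.G / (rchild.H + kEps)));
    left[parent.id] = lchild.id;
    right[parent.id] = rchild.id;

    leaves.push_back(std::move(lchild));
    leaves.push_back(std::move(rchild));
    ++n_leaves;
  }
}

double tree_predict_row(const NumericMatrix& nodes, const NumericMatrix& X,
                        int i) {
  int cur = 0;
  while (nodes(cur, 0) >= 0) {
    const int j = static_cast<int>(nodes(cur, 0));
    cur = (X(i, j) <= nodes(cur, 1)) ? static_cast<int>(nodes(cur, 2))
                                     : static_cast<int>(nodes(cur, 3));
  }
  return nodes(cur, 4);
}

} // namespace

// [[Rcpp::export]]
List gbdt_train_cpp(NumericMatrix X, NumericVector y, int n_estimators,
                    double learning_rate, int max_depth, int num_leaves,
                    int min_data) {
  TrainData td;
  td.n = X.nrow();
  td.p = X.ncol();
  td.x.resize(static_cast<size_t>(td.n) * td.p);
  for (int j = 0; j < td.p; ++j) {
    for (int i = 0; i < td.n; ++i) {
      td.x[static_cast<size_t>(j) * td.n + i] = X(i, j);
    }
  }
  td.order.resize(td.x.size());
  for (int j = 0; j < td.p; ++j) {
    int* ord = &td.order[static_cast<size_t>(j) * td.n];
    for (int i = 0; i < td.n; ++i) ord[i] = i;
    const double* col = &td.x[static_cast<size_t>(j) * td.n];
    std::stable_sort(ord, ord + td.n,
                     [col](int a, int b) { return col[a] < col[b]; });
  }

  const int n = td.n;
  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  ybar = std::min(1.0 - 1e-6, std::max(1e-6, ybar));
  const double base = std::log(ybar / (1.0 - ybar));

  std::vector<double> F(n, base), g(n), h(n);
  std::vector<char> in_node(n, 0);
  List trees(n_estimators);
  for (int m = 0; m < n_estimators; ++m) {
    for (int i = 0; i < n; ++i) {
      const double p = 1.0 / (1.0 + std::exp(-F[i]));
      g[i] = p - y[i];
      h[i] = std::max(p * (1.0 - p), 1e-16);
    }
    std::vector<int> feature, left, right;
    std::vector<double> threshold, value;
    grow_tree(td, g, h, max_depth, num_leaves, min_data, learning_rate,
              in_node, feature, threshold, left, right, value);
    const int nn = feature.size();
    NumericMatrix nodes(nn, 5);
    for (int k = 0; k < nn; ++k) {
      nodes(k, 0) = feature[k];
      nodes(k, 1) = threshold[k];
      nodes(k, 2) = left[k];
      nodes(k, 3) = right[k];
      nodes(k, 4) = value[k];
    }
    trees[m] = nodes;
    for (int i = 0; i < n; ++i) F[i] += tree_predict_row(nodes, X, i);
  }
  return List::create(_["base_score"] = base, _["trees"] = trees);
}

// [[Rcpp::export]]
NumericVector gbdt_predict_cpp(List model, NumericMatrix X) {
  const double base = as<double>(model["base_score"]);
  List trees = model["trees"];
  const int n = X.nrow();
  NumericVector out(n, base);
  for (int m = 0; m < trees.size(); ++m) {
    NumericMatrix nodes = trees[m];
    for (int i = 0; i < n; ++i) out[i] += tree_predict_row(nodes, X, i);
  }
  for (int i = 0; i < n; ++i) out[i] = 1.0 / (1.0 + std::exp(-out[i]));
  return out;
}
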