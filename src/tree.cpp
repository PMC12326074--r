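// CART-style regression trees for the gradient-boosting learner.
// Features are presorted once per ensemble; each node scans every allowed
// feature in global sorted order restricted to its members, so split search
// is O(n_total) per feature with no per-node sorting. Deterministic:
// features scanned in index order and a split must strictly improve on the
// incumbent to replace it.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct Node {
  int feature = -1;     // -1 for leaf
  double threshold = 0; // go left if x <= threshold
  int left = -1, right = -1;
  double value = 0;     // mean response of training rows in the node
};

struct Presort {
  // ord[f] = row indices sorted ascending by feature f
  std::vector<std::vector<int>> ord;
};

void grow(const NumericMatrix& X, const std::vector<double>& y,
          const Presort& ps, std::vector<char>& member, int n_node,
          int depth, int max_depth, int min_leaf,
          const std::vector<int>& cols, std::vector<Node>& nodes,
          int node_idx, std::vector<int>& buf) {
  double sum = 0.0;
  const int n_total = X.nrow();
  // members are recovered via any feature's sorted order; cheaper: scan flags
  for (int r = 0; r < n_total; ++r) if (member[r]) sum += y[r];
  const double mean = sum / n_node;
  nodes[node_idx].value = mean;
  if (depth >= max_depth || n_node < 2 * min_leaf) return;

  double base_sse = 0.0;
  for (int r = 0; r < n_total; ++r) {
    if (member[r]) { double d = y[r] - mean; base_sse += d * d; }
  }
  if (base_sse <= 1e-12) return;

  int best_f = -1;
  double best_gain = 1e-10, best_thr = 0.0;

  for (int f : cols) {
    const std::vector<int>& order = ps.ord[f];
    int m = 0;
    for (int r : order) if (member[r]) buf[m++] = r; // members, sorted by f
    double ls = 0.0, rs = sum;
    for (int i = 0; i < m - 1; ++i) {
      const int ri = buf[i];
      ls += y[ri]; rs -= y[ri];
      const int nl = i + 1, nr = m - nl;
      if (nl < min_leaf) continue;
      if (nr < min_leaf) break;
      const double xa = X(ri, f), xb = X(buf[i + 1], f);
      if (xb <= xa) continue; // no valid threshold between equal values
      const double gain = ls * ls / nl + rs * rs / nr - sum * sum / n_node;
      if (gain > best_gain) {
        best_gain = gain; best_f = f;
        best_thr = xa + (xb - xa) / 2.0;
      }
    }
  }
  if (best_f < 0) return;

  std::vector<char> lmember(n_total, 0);
  int nl = 0;
  for (int r = 0; r < n_total; ++r) {
    if (member[r] && X(r, best_f) <= best_thr) { lmember[r] = 1; ++nl; }
  }
  const int nr = n_node - nl;
  if (nl == 0 || nr == 0) return; // numerical guard

  // right members in place: member minus left
  for (int r = 0; r < n_total; ++r) if (lmember[r]) member[r] = 0;

  nodes[node_idx].feature = best_f;
  nodes[node_idx].threshold = best_thr;
  nodes.push_back(Node());
  const int li = (int)nodes.size() - 1;
  nodes[node_idx].left = li;
  grow(X, y, ps, lmember, nl, depth + 1, max_depth, min_leaf, cols, nodes,
       li, buf);
  nodes.push_back(Node());
  const int rix = (int)nodes.size() - 1;
  nodes[node_idx].right = rix;
  grow(X, y, ps, member, nr, depth + 1, max_depth, min_leaf, cols, nodes,
       rix, buf);
}

List tree_to_list(const std::vector<Node>& nodes) {
  const int m = nodes.size();
  IntegerVector feature(m), left(m), right(m);
  NumericVector threshold(m), value(m);
  for (int i = 0; i < m; ++i) {
    feature[i] = nodes[i].feature;
    threshold[i] = nodes[i].threshold;
    left[i] = nodes[i].left;
    right[i] = nodes[i].right;
    value[i] = nodes[i].value;
  }
  return List::create(_["feature"] = feature, _["threshold"] = threshold,
                      _["left"] = left, _["right"] = right,
                      _["value"] = value);
}

double predict_row(const std::vector<Node>& nodes, const NumericMatrix& X,
                   int i) {
  int node = 0;
  while (nodes[node].feature >= 0) {
    node = (X(i, nodes[node].feature) <= nodes[node].threshold)
               ? nodes[node].left : nodes[node].right;
  }
  return nodes[node].value;
}

} // namespace

// Boosting loop: squared-error gradient boosting with shrinkage.
// row_samples / col_samples: per-tree 0-based index vectors drawn in R so
// that RNG behaviour stays on the R side.
// [[Rcpp::export(name = ".gbdt_boost_cpp")]]
List gbdt_boost_cpp(NumericMatrix X, NumericVector y, List row_samples,
                    List col_samples, int max_depth, int min_leaf,
                    double learning_rate, double f0) {
  const int n = X.nrow(), p = X.ncol(), n_trees = row_samples.size();
  Presort ps;
  ps.ord.resize(p);
  for (int f = 0; f < p; ++f) {
    ps.ord[f].resize(n);
    for (int i = 0; i < n; ++i) ps.ord[f][i] = i;
    std::stable_sort(ps.ord[f].begin(), ps.ord[f].end(),
                     [&](int a, int b) { return X(a, f) < X(b, f); });
  }
  std::vector<double> pred(n, f0), resid(n);
  std::vector<int> buf(n);
  List trees(n_trees);
  for (int m = 0; m < n_trees; ++m) {
    IntegerVector rows = row_samples[m];
    IntegerVector cv = col_samples[m];
    std::vector<int> cols(cv.begin(), cv.end());
    for (int i = 0; i < n; ++i) resid[i] = y[i] - pred[i];
    std::vector<char> member(n, 0);
    for (int r : rows) member[r] = 1;
    std::vector<Node> nodes(1);
    grow(X, resid, ps, member, rows.size(), 0, max_depth, min_leaf, cols,
         nodes, 0, buf);
    for (int i = 0; i < n; ++i) {
      pred[i] += learning_rate * predict_row(nodes, X, i);
    }
    trees[m] = tree_to_list(nodes);
  }
  return trees;
}

// [[Rcpp::export(name = ".predict_tree_cpp")]]
NumericVector predict_tree_cpp(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"],
                right = tree["right"];
  NumericVector threshold = tree["threshold"], value = tree["value"];
  const int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] >= 0) {
      node = (X(i, feature[node]) <= threshold[node]) ? left[node]
                                                      : right[node];
    }
    out[i] = value[node];
  }
  return out;
}
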