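#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Gradient-boosted regression trees with squared-error loss.
// Greedy variance-reduction splitting with exact enumeration of candidate
// thresholds (midpoints between distinct observed values of each SNP at the
// node). Ties between equal-gain splits are broken by lowest feature index,
// then lowest threshold (the scan order). Deterministic: no subsampling.

struct Node {
  int feature;      // -1 for leaf
  double threshold; // go left if x <= threshold
  int left, right;  // 0-based node indices, -1 if leaf
  double value;     // leaf prediction (mean residual)
  double gain;      // squared-error reduction achieved by the split
  int n;            // training samples in the node
};

struct SplitResult {
  bool found = false;
  int feature = -1;
  double threshold = 0.0;
  double gain = 0.0;
};

static SplitResult best_split(const NumericMatrix& X,
                              const std::vector<double>& resid,
                              const std::vector<int>& samples,
                              const std::vector<std::vector<int>>& order,
                              std::vector<char>& member,
                              int min_leaf) {
  const int m = X.ncol();
  const int nn = (int)samples.size();
  double sum = 0.0;
  for (int i : samples) sum += resid[i];
  const double base = sum * sum / nn;
  SplitResult best;
  for (int i : samples) member[i] = 1;
  std::vector<int> idx;
  idx.reserve(nn);
  for (int j = 0; j < m; ++j) {
    idx.clear();
    for (int i : order[j]) if (member[i]) idx.push_back(i);
    // scan sorted member values; candidate cut between distinct values
    double sl = 0.0;
    int nl = 0;
    for (int k = 0; k < nn - 1; ++k) {
      sl += resid[idx[k]];
      ++nl;
      double xv = X(idx[k], j), xn = X(idx[k + 1], j);
      if (xn <= xv) continue; // not a boundary between distinct values
      if (nl < min_leaf || nn - nl < min_leaf) continue;
      double sr = sum - sl;
      double gain = sl * sl / nl + sr * sr / (nn - nl) - base;
      if (gain > best.gain + 1e-12 ||
          (!best.found && gain > 1e-12)) {
        best.found = true;
        best.feature = j;
        best.threshold = 0.5 * (xv + xn);
        best.gain = gain;
      }
    }
  }
  for (int i : samples) member[i] = 0;
  return best;
}

static int build_node(const NumericMatrix& X, const std::vector<double>& resid,
                      std::vector<int>& samples,
                      const std::vector<std::vector<int>>& order,
                      std::vector<char>& member,
                      int depth, int max_depth, int min_leaf,
                      std::vector<Node>& nodes) {
  Node nd;
  const int nn = (int)samples.size();
  double sum = 0.0;
  for (int i : samples) sum += resid[i];
  nd.feature = -1;
  nd.threshold = 0.0;
  nd.left = nd.right = -1;
  nd.value = sum / nn;
  nd.gain = 0.0;
  nd.n = nn;
  int my_id = (int)nodes.size();
  nodes.push_back(nd);
  if (depth >= max_depth || nn < 2 * min_leaf) return my_id;
  SplitResult sp = best_split(X, resid, samples, order, member, min_leaf);
  if (!sp.found) return my_id;
  std::vector<int> left_s, right_s;
  left_s.reserve(nn);
  right_s.reserve(nn);
  for (int i : samples) {
    if (X(i, sp.feature) <= sp.threshold) left_s.push_back(i);
    else right_s.push_back(i);
  }
  nodes[my_id].feature = sp.feature;
  nodes[my_id].threshold = sp.threshold;
  nodes[my_id].gain = sp.gain;
  int l = build_node(X, resid, left_s, order, member, depth + 1, max_depth,
                     min_leaf, nodes);
  int r = build_node(X, resid, right_s, order, member, depth + 1, max_depth,
                     min_leaf, nodes);
  nodes[my_id].left = l;
  nodes[my_id].right = r;
  return my_id;
}

static double tree_predict_row(const std::vector<Node>& nodes,
                               const NumericMatrix& X, int i) {
  int cur = 0;
  while (nodes[cur].feature >= 0) {
    cur = (X(i, nodes[cur].feature) <= nodes[cur].threshold)
      ? nodes[cur].left : nodes[cur].right;
  }
  return nodes[cur].value;
}

static NumericMatrix pack_tree(const std::vector<Node>& nodes) {
  NumericMatrix out((int)nodes.size(), 7);
  for (size_t k = 0; k < nodes.size(); ++k) {
    out(k, 0) = nodes[k].feature + 1; // 1-based; 0 = leaf
    out(k, 1) = nodes[k].threshold;
    out(k, 2) = nodes[k].left + 1;    // 1-based; 0 = none
    out(k, 3) = nodes[k].right + 1;
    out(k, 4) = nodes[k].value;
    out(k, 5) = nodes[k].gain;
    out(k, 6) = nodes[k].n;
  }
  colnames(out) = CharacterVector::create("feature", "threshold", "left",
                                          "right", "value", "gain", "n");
  return out;
}

// [[Rcpp::export(name = ".gbm_fit_cpp")]]
List gbm_fit_cpp(const NumericVector& y, const NumericMatrix& X,
                 int ntree, double learning_rate, int max_depth,
                 int min_leaf, int stopping_rounds, double stopping_tol) {
  const int n = X.nrow(), m = X.ncol();
  std::vector<std::vector<int>> order(m);
  for (int j = 0; j < m; ++j) {
    order[j].resize(n);
    for (int i = 0; i < n; ++i) order[j][i] = i;
    const int jj = j;
    std::stable_sort(order[j].begin(), order[j].end(),
                     [&X, jj](int a, int b) { return X(a, jj) < X(b, jj); });
  }
  double mu = 0.0;
  for (int i = 0; i < n; ++i) mu += y[i];
  mu /= n;
  std::vector<double> pred(n, mu), resid(n);
  std::vector<char> member(n, 0);
  std::vector<int> all(n);
  for (int i = 0; i < n; ++i) all[i] = i;

  List trees;
  std::vector<double> rmse_trace;
  double best_rmse = R_PosInf;
  int stall = 0;
  for (int t = 0; t < ntree; ++t) {
    for (int i = 0; i < n; ++i) resid[i] = y[i] - pred[i];
    std::vector<Node> nodes;
    std::vector<int> samples = all;
    build_node(X, resid, samples, order, member, 0, max_depth, min_leaf, nodes);
    if (nodes.size() == 1 && nodes[0].feature < 0 &&
        std::fabs(nodes[0].value) < 1e-15) {
      break; // nothing left to fit
    }
    for (int i = 0; i < n; ++i) {
      pred[i] += learning_rate * tree_predict_row(nodes, X, i);
    }
    trees.push_back(pack_tree(nodes));
    double sse = 0.0;
    for (int i = 0; i < n; ++i) {
      double d = y[i] - pred[i];
      sse += d * d;
    }
    double rmse = std::sqrt(sse / n);
    rmse_trace.push_back(rmse);
    if (rmse < best_rmse - stopping_tol) {
      best_rmse = rmse;
      stall = 0;
    } else {
      ++stall;
      if (stall >= stopping_rounds) break;
    }
    if (rmse <= 0.0) break;
  }
  return List::create(_["mu"] = mu, _["trees"] = trees,
                      _["rmse_trace"] = NumericVector(rmse_trace.begin(),
                                                      rmse_trace.end()),
                      _["train_pred"] = NumericVector(pred.begin(), pred.end()));
}

// [[Rcpp::export(name = ".gbm_predict_cpp")]]
NumericVector gbm_predict_cpp(List trees, double mu, double learning_rate,
                              const NumericMatrix& X) {
  const int n = X.nrow();
  NumericVector out(n, mu);
  for (int t = 0; t < trees.size(); ++t) {
    NumericMatrix tm = trees[t];
    for (int i = 0; i < n; ++i) {
      int cur = 0;
      while (tm(cur, 0) > 0) {
        int f = (int)tm(cur, 0) - 1;
        cur = (X(i, f) <= tm(cur, 1)) ? (int)tm(cur, 2) - 1
                                      : (int)tm(cur, 3) - 1;
      }
      out[i] += learning_rate * tm(cur, 4);
    }
  }
  return out;
}
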