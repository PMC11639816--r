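// Histogram-based CART growers.
//
// Features are pre-binned in R (quantile bins, at most 256 per feature); a
// split is "bin <= t goes left". Two growers share the machinery:
//  * reg: second-order boosting tree on per-row gradient/hessian
//    (leaf value -G/(H+lambda), gain in the usual second-order form)
//  * cls: gini/entropy classification tree with sample weights and
//    per-node feature subsampling (bagged-forest member)
#include <Rcpp.h>
#include <random>
#include <vector>
using namespace Rcpp;

namespace {

struct Node {
  std::vector<int> rows;
  int depth;
  int id;
};

// grow a flat tree; out-params are parallel arrays describing nodes
struct FlatTree {
  std::vector<int> feature, thr, left, right;
  std::vector<double> value;          // reg leaves (0 for internal)
  std::vector<double> leaf_counts;    // cls leaves, K per node
  int add_node() {
    feature.push_back(-1); thr.push_back(-1);
    left.push_back(-1); right.push_back(-1);
    value.push_back(0.0);
    return (int)feature.size() - 1;
  }
};

}  // namespace

// [[Rcpp::export(name = ".grow_reg_tree")]]
List grow_reg_tree(IntegerMatrix Xb, NumericVector grad, NumericVector hess,
                   IntegerVector rows0, int nbins, int max_depth,
                   double lambda, double gamma, double min_child_weight,
                   int min_data_in_leaf) {
  const int p = Xb.ncol();
  FlatTree T;
  NumericVector importance(p);
  std::vector<Node> stack;
  Node root;
  root.rows.assign(rows0.begin(), rows0.end());
  root.depth = 0;
  root.id = T.add_node();
  stack.push_back(std::move(root));

  std::vector<double> hg(nbins), hh(nbins);
  std::vector<int> hc(nbins);

  while (!stack.empty()) {
    Node nd = std::move(stack.back());
    stack.pop_back();
    double G = 0, H = 0;
    for (int r : nd.rows) { G += grad[r]; H += hess[r]; }
    const double parent_score = G * G / (H + lambda);
    T.value[nd.id] = -G / (H + lambda);
    if (nd.depth >= max_depth || (int)nd.rows.size() < 2 * min_data_in_leaf)
      continue;

    double best_gain = 0;
    int best_f = -1, best_t = -1;
    for (int f = 0; f < p; ++f) {
      std::fill(hg.begin(), hg.end(), 0.0);
      std::fill(hh.begin(), hh.end(), 0.0);
      std::fill(hc.begin(), hc.end(), 0);
      for (int r : nd.rows) {
        int b = Xb(r, f);
        hg[b] += grad[r]; hh[b] += hess[r]; hc[b] += 1;
      }
      double GL = 0, HL = 0; int CL = 0;
      for (int b = 0; b < nbins - 1; ++b) {
        GL += hg[b]; HL += hh[b]; CL += hc[b];
        if (CL < min_data_in_leaf) continue;
        int CR = (int)nd.rows.size() - CL;
        if (CR < min_data_in_leaf) break;
        double HR = H - HL;
        if (HL < min_child_weight || HR < min_child_weight) continue;
        double GR = G - GL;
        double gain = 0.5 * (GL * GL / (HL + lambda) + GR * GR / (HR + lambda)
                             - parent_score) - gamma;
        if (gain > best_gain) { best_gain = gain; best_f = f; best_t = b; }
      }
    }
    if (best_f < 0) continue;

    Node L, R;
    for (int r : nd.rows)
      (Xb(r, best_f) <= best_t ? L.rows : R.rows).push_back(r);
    T.feature[nd.id] = best_f;
    T.thr[nd.id] = best_t;
    importance[best_f] += best_gain;
    L.depth = R.depth = nd.depth + 1;
    L.id = T.add_node(); R.id = T.add_node();
    T.left[nd.id] = L.id; T.right[nd.id] = R.id;
    stack.push_back(std::move(L));
    stack.push_back(std::move(R));
  }
  return List::create(_["feature"] = wrap(T.feature), _["thr"] = wrap(T.thr),
                      _["left"] = wrap(T.left), _["right"] = wrap(T.right),
                      _["value"] = wrap(T.value), _["importance"] = importance);
}

// [[Rcpp::export(name = ".predict_reg_tree")]]
NumericVector predict_reg_tree(IntegerMatrix Xb, IntegerVector feature,
                               IntegerVector thr, IntegerVector left,
                               IntegerVector right, NumericVector value) {
  const int n = Xb.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int nd = 0;
    while (feature[nd] >= 0)
      nd = (Xb(i, feature[nd]) <= thr[nd]) ? left[nd] : right[nd];
    out[i] = value[nd];
  }
  return out;
}

static inline double impurity(const std::vector<double>& cnt, double tot,
                              int K, int criterion) {
  if (tot <= 0) return 0.0;
  double imp = 0.0;
  if (criterion == 0) {  // gini
    double s = 0;
    for (int k = 0; k < K; ++k) { double q = cnt[k] / tot; s += q * q; }
    imp = 1.0 - s;
  } else {               // entropy
    for (int k = 0; k < K; ++k) {
      double q = cnt[k] / tot;
      if (q > 0) imp -= q * std::log2(q);
    }
  }
  return imp;
}

// [[Rcpp::export(name = ".grow_cls_tree")]]
List grow_cls_tree(IntegerMatrix Xb, IntegerVector y, NumericVector w,
                   IntegerVector rows0, int nbins, int K, int max_depth,
                   int min_samples_split, int min_samples_leaf,
                   int max_features, int criterion, int seed) {
  const int p = Xb.ncol();
  FlatTree T;
  NumericVector importance(p);
  std::mt19937 rng(seed);
  std::vector<int> featidx(p);
  for (int f = 0; f < p; ++f) featidx[f] = f;

  std::vector<Node> stack;
  Node root;
  root.rows.assign(rows0.begin(), rows0.end());
  root.depth = 0;
  root.id = T.add_node();
  stack.push_back(std::move(root));
  std::vector<std::vector<double>> leaves;  // class counts per node id
  leaves.emplace_back();

  std::vector<double> hw((size_t)nbins * K);
  std::vector<int> hc(nbins);

  while (!stack.empty()) {
    Node nd = std::move(stack.back());
    stack.pop_back();
    std::vector<double> cnt(K, 0.0);
    double tot = 0;
    for (int r : nd.rows) { cnt[y[r]] += w[r]; tot += w[r]; }
    if ((int)leaves.size() <= nd.id) leaves.resize(nd.id + 1);
    leaves[nd.id] = cnt;
    const double par_imp = impurity(cnt, tot, K, criterion);
    if (nd.depth >= max_depth || (int)nd.rows.size() < min_samples_split ||
        par_imp <= 0.0)
      continue;

    // per-node feature subsample without replacement
    int m = std::min(max_features, p);
    for (int i = 0; i < m; ++i) {
      std::uniform_int_distribution<int> d(i, p - 1);
      std::swap(featidx[i], featidx[d(rng)]);
    }

    double best_gain = 1e-12;
    int best_f = -1, best_t = -1;
    for (int fi = 0; fi < m; ++fi) {
      int f = featidx[fi];
      std::fill(hw.begin(), hw.end(), 0.0);
      std::fill(hc.begin(), hc.end(), 0);
      for (int r : nd.rows) {
        int b = Xb(r, f);
        hw[(size_t)b * K + y[r]] += w[r];
        hc[b] += 1;
      }
      std::vector<double> cl(K, 0.0);
      double wl = 0; int CL = 0;
      for (int b = 0; b < nbins - 1; ++b) {
        for (int k = 0; k < K; ++k) cl[k] += hw[(size_t)b * K + k];
        CL += hc[b];
        if (CL < min_samples_leaf) continue;
        int CR = (int)nd.rows.size() - CL;
        if (CR < min_samples_leaf) break;
        wl = 0; for (int k = 0; k < K; ++k) wl += cl[k];
        double wr = tot - wl;
        if (wl <= 0 || wr <= 0) continue;
        std::vector<double> cr(K);
        for (int k = 0; k < K; ++k) cr[k] = cnt[k] - cl[k];
        double gain = par_imp
          - (wl / tot) * impurity(cl, wl, K, criterion)
          - (wr / tot) * impurity(cr, wr, K, criterion);
        if (gain > best_gain) { best_gain = gain; best_f = f; best_t = b; }
      }
    }
    if (best_f < 0) continue;

    Node L, R;
    for (int r : nd.rows)
      (Xb(r, best_f) <= best_t ? L.rows : R.rows).push_back(r);
    T.feature[nd.id] = best_f;
    T.thr[nd.id] = best_t;
    importance[best_f] += tot * best_gain;
    L.depth = R.depth = nd.depth + 1;
    L.id = T.add_node(); R.id = T.add_node();
    T.left[nd.id] = L.id; T.right[nd.id] = R.id;
    stack.push_back(std::move(L));
    stack.push_back(std::move(R));
  }

  NumericMatrix leaf_counts((int)T.feature.size(), K);
  for (size_t i = 0; i < T.feature.size(); ++i)
    if (i < leaves.size() && (int)leaves[i].size() == K)
      for (int k = 0; k < K; ++k) leaf_counts((int)i, k) = leaves[i][k];
  return List::create(_["feature"] = wrap(T.feature), _["thr"] = wrap(T.thr),
                      _["left"] = wrap(T.left), _["right"] = wrap(T.right),
                      _["leaf_counts"] = leaf_counts,
                      _["importance"] = importance);
}

// [[Rcpp::export(name = ".predict_cls_tree")]]
NumericMatrix predict_cls_tree(IntegerMatrix Xb, IntegerVector feature,
                               IntegerVector thr, IntegerVector left,
                               IntegerVector right, NumericMatrix leaf_counts) {
  const int n = Xb.nrow(), K = leaf_counts.ncol();
  NumericMatrix out(n, K);
  for (int i = 0; i < n; ++i) {
    int nd = 0;
    while (feature[nd] >= 0)
      nd = (Xb(i, feature[nd]) <= thr[nd]) ? left[nd] : right[nd];
    double tot = 0;
    for (int k = 0; k < K; ++k) tot += leaf_counts(nd, k);
    for (int k = 0; k < K; ++k)
      out(i, k) = tot > 0 ? leaf_counts(nd, k) / tot : 1.0 / K;
  }
  return out;
}
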