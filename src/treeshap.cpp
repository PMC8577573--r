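// Interventional (marginal-expectation) Shapley values for forests of
// regression trees.  For one foreground row x and one background row z,
// the coalition game is f(S) = tree prediction where features in S take
// x's values and the rest take z's: for each leaf the game restricted to
// its path is a product of per-feature indicators, whose Shapley value has
// a closed combinatorial form.  Features on a leaf's path classify as
// "must-in" (only x satisfies their splits), "must-out" (only z does),
// "free" (both do) or "dead" (neither; the leaf contributes nothing), and
// all must-in features of a leaf share one weight, as do all must-out
// ones.  Averaging over the background sample gives marginal-expectation
// Shapley values; efficiency (baseline + sum(phi) = f(x)) holds by
// construction.
//
// Trees are passed as matrices with columns
//   0: left child, 1: right child (0-based; -1 at leaves)
//   2: split variable (0-based; -1 at leaves)
//   3: split value   (x goes left iff x[var] <= split)
//   4: node prediction (used at leaves)

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct TreeView {
  const double *left, *right, *var, *split, *pred;
  int n_nodes;
};

// Shapley coalition weights, flattened: W[m * (p + 1) + free] =
// sum_j C(free, j) (m+j)! (p-m-j-1)! / p!   (log-space for stability)
static std::vector<double> weight_table(int p) {
  std::vector<double> W((size_t)p * (p + 1), 0.0);
  double lgp = std::lgamma(p + 1.0);
  for (int m = 0; m < p; ++m) {
    int maxfree = p - 1 - m;
    for (int fr = 0; fr <= maxfree; ++fr) {
      double s = 0.0;
      for (int j = 0; j <= fr; ++j) {
        double lterm = std::lgamma(fr + 1.0) - std::lgamma(j + 1.0) -
                       std::lgamma(fr - j + 1.0) + std::lgamma(m + j + 1.0) +
                       std::lgamma(p - m - j + 0.0) - lgp;
        s += std::exp(lterm);
      }
      W[(size_t)m * (p + 1) + fr] = s;
    }
  }
  return W;
}

struct Walker {
  TreeView tree;
  const double *x, *z;
  int p;
  const double *W;  // flat weight table
  // per-feature path state
  std::vector<int> cntAfail, cntBfail, onPath;
  std::vector<int> pathFeat;
  int m, o;  // counts of must-in / must-out features on the current path
  double *phi;

  void init(int p_) {
    p = p_;
    cntAfail.assign(p, 0);
    cntBfail.assign(p, 0);
    onPath.assign(p, 0);
    pathFeat.clear();
    pathFeat.reserve(64);
    m = 0;
    o = 0;
  }

  // class of a feature from its fail flags: 0 free, 1 must-in, 2 must-out,
  // 3 dead
  static inline int cls(bool afail, bool bfail) {
    return (afail ? 2 : 0) + (bfail ? 1 : 0);
  }

  void visit(int node) {
    int v = (int)tree.var[node];
    if (v < 0) {  // leaf (dead paths were pruned during descent)
      double val = tree.pred[node];
      int fr = p - m - o;
      double c_in = (m > 0) ? val * W[(size_t)(m - 1) * (p + 1) + fr] : 0.0;
      double c_out = (o > 0) ? val * W[(size_t)m * (p + 1) + fr] : 0.0;
      if (m > 0 || o > 0) {
        for (int f : pathFeat) {
          bool af = cntAfail[f] > 0, bf = cntBfail[f] > 0;
          if (af == bf) continue;          // free
          if (bf) phi[f] += c_in;          // must-in: only x satisfies
          else    phi[f] -= c_out;         // must-out: only z satisfies
        }
      }
      return;
    }
    bool xleft = x[v] <= tree.split[node];
    bool zleft = z[v] <= tree.split[node];
    for (int side = 0; side < 2; ++side) {
      bool afail = side == 0 ? !xleft : xleft;
      bool bfail = side == 0 ? !zleft : zleft;
      if (afail && bfail) continue;  // no hybrid reaches this subtree
      bool newf = onPath[v] == 0;
      int oldc = newf ? 0 : cls(cntAfail[v] > 0, cntBfail[v] > 0);
      ++onPath[v];
      cntAfail[v] += afail;
      cntBfail[v] += bfail;
      int newc = cls(cntAfail[v] > 0, cntBfail[v] > 0);
      if (newc != 3) {  // subtree alive
        if (oldc != newc) {
          if (oldc == 1) --m; else if (oldc == 2) --o;
          if (newc == 1) ++m; else if (newc == 2) ++o;
        }
        if (newf) pathFeat.push_back(v);
        visit(side == 0 ? (int)tree.left[node] : (int)tree.right[node]);
        if (newf) pathFeat.pop_back();
        if (oldc != newc) {
          if (newc == 1) --m; else if (newc == 2) --o;
          if (oldc == 1) ++m; else if (oldc == 2) ++o;
        }
      }
      --onPath[v];
      cntAfail[v] -= afail;
      cntBfail[v] -= bfail;
    }
  }
};

static double tree_predict(const TreeView &t, const double *row) {
  int node = 0;
  while ((int)t.var[node] >= 0) {
    node = row[(int)t.var[node]] <= t.split[node] ? (int)t.left[node]
                                                  : (int)t.right[node];
  }
  return t.pred[node];
}

static std::vector<TreeView> make_views(const List &forest,
                                        std::vector<NumericMatrix> &keep) {
  std::vector<TreeView> views;
  keep.reserve(forest.size());
  for (int t = 0; t < forest.size(); ++t) {
    keep.push_back(as<NumericMatrix>(forest[t]));
    NumericMatrix &m = keep.back();
    TreeView v;
    v.n_nodes = m.nrow();
    v.left = &m(0, 0);
    v.right = &m(0, 1);
    v.var = &m(0, 2);
    v.split = &m(0, 3);
    v.pred = &m(0, 4);
    views.push_back(v);
  }
  return views;
}

}  // namespace

// [[Rcpp::export]]
List treeshap_interventional_cpp(List forest, NumericMatrix X,
                                 NumericMatrix Z) {
  int J = X.nrow(), p = X.ncol(), B = Z.nrow();
  if (Z.ncol() != p) stop("background and foreground column mismatch");
  if (B == 0) stop("background sample is empty");
  std::vector<NumericMatrix> keep;
  std::vector<TreeView> trees = make_views(forest, keep);
  int T = (int)trees.size();
  std::vector<double> W = weight_table(p);

  // row-major copies for cache-friendly access
  std::vector<double> Xr((size_t)J * p), Zr((size_t)B * p);
  for (int j = 0; j < J; ++j)
    for (int k = 0; k < p; ++k) Xr[(size_t)j * p + k] = X(j, k);
  for (int b = 0; b < B; ++b)
    for (int k = 0; k < p; ++k) Zr[(size_t)b * p + k] = Z(b, k);

  double baseline = 0.0;
  for (int b = 0; b < B; ++b) {
    double s = 0.0;
    for (const auto &t : trees) s += tree_predict(t, &Zr[(size_t)b * p]);
    baseline += s / T;
  }
  baseline /= B;

  std::vector<double> acc((size_t)J * p, 0.0);
  Walker w;
  w.init(p);
  w.W = W.data();
  // tree-outer ordering keeps each tree's node arrays hot in cache
  for (int t = 0; t < T; ++t) {
    w.tree = trees[t];
    for (int j = 0; j < J; ++j) {
      w.x = &Xr[(size_t)j * p];
      w.phi = &acc[(size_t)j * p];
      for (int b = 0; b < B; ++b) {
        w.z = &Zr[(size_t)b * p];
        w.visit(0);
      }
    }
    Rcpp::checkUserInterrupt();
  }
  NumericMatrix phi(J, p);
  double denom = (double)B * T;
  for (int j = 0; j < J; ++j)
    for (int k = 0; k < p; ++k) phi(j, k) = acc[(size_t)j * p + k] / denom;
  return List::create(_["phi"] = phi, _["baseline"] = baseline);
}

// [[Rcpp::export]]
NumericVector forest_predict_cpp(List forest, NumericMatrix X) {
  int J = X.nrow(), p = X.ncol();
  std::vector<NumericMatrix> keep;
  std::vector<TreeView> trees = make_views(forest, keep);
  NumericVector out(J);
  std::vector<double> row(p);
  for (int j = 0; j < J; ++j) {
    for (int k = 0; k < p; ++k) row[k] = X(j, k);
    double s = 0.0;
    for (const auto &t : trees) s += tree_predict(t, row.data());
    out[j] = s / trees.size();
  }
  return out;
}
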