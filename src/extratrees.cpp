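#include <Rcpp.h>
#include <random>
#include <vector>
#include <stack>
using namespace Rcpp;

// Extremely-randomized regression trees with impurity importance.
// One tree node: candidate features are sampled without replacement,
// each gets a uniform random threshold between its node min and max, and
// the best variance reduction among candidates wins. Importance for a
// feature accumulates the (unnormalized) sum-of-squares reduction of the
// splits it provides; with y standardized, importance / (n_trees * n)
// is the fraction of variance explained attributable to the feature.

struct Node {
  std::vector<int> idx;
};

// [[Rcpp::export(name = ".et_importance")]]
NumericVector et_importance(NumericMatrix X, NumericVector y,
                            int n_trees, int mtry, int min_node,
                            int seed) {
  const int n = X.nrow(), p = X.ncol();
  NumericVector imp(p);
  if (n < 2 || p < 1) return imp;
  std::mt19937 rng(static_cast<unsigned>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::vector<int> feat(p);

  for (int t = 0; t < n_trees; ++t) {
    std::stack<Node> work;
    Node root;
    root.idx.resize(n);
    for (int i = 0; i < n; ++i) root.idx[i] = i;
    work.push(std::move(root));

    while (!work.empty()) {
      Node node = std::move(work.top());
      work.pop();
      const int m = (int)node.idx.size();
      if (m < 2 * min_node) continue;
      double sy = 0.0, syy = 0.0;
      for (int i : node.idx) { sy += y[i]; syy += y[i] * y[i]; }
      double ss_node = syy - sy * sy / m;
      if (ss_node <= 1e-12) continue;

      // partial Fisher-Yates to draw mtry candidate features
      for (int j = 0; j < p; ++j) feat[j] = j;
      int k = std::min(mtry, p);
      double best_red = -1.0;
      int best_f = -1;
      double best_thr = 0.0;
      for (int c = 0; c < k; ++c) {
        int r = c + (int)(unif(rng) * (p - c));
        if (r >= p) r = p - 1;
        std::swap(feat[c], feat[r]);
        int f = feat[c];
        double lo = R_PosInf, hi = R_NegInf;
        for (int i : node.idx) {
          double v = X(i, f);
          if (v < lo) lo = v;
          if (v > hi) hi = v;
        }
        if (hi <= lo) continue;
        double thr = lo + unif(rng) * (hi - lo);
        double syl = 0.0, syyl = 0.0; int nl = 0;
        for (int i : node.idx) {
          if (X(i, f) <= thr) { syl += y[i]; syyl += y[i] * y[i]; ++nl; }
        }
        int nr = m - nl;
        if (nl == 0 || nr == 0) continue;
        double syr = sy - syl, syyr = syy - syyl;
        double red = ss_node - (syyl - syl * syl / nl)
                             - (syyr - syr * syr / nr);
        if (red > best_red) { best_red = red; best_f = f; best_thr = thr; }
      }
      if (best_f < 0) continue;
      imp[best_f] += best_red;
      Node left, right;
      for (int i : node.idx) {
        if (X(i, best_f) <= best_thr) left.idx.push_back(i);
        else right.idx.push_back(i);
      }
      work.push(std::move(left));
      work.push(std::move(right));
    }
  }
  for (int j = 0; j < p; ++j) imp[j] /= (double)n_trees * n;
  return imp;
}
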