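#include <Rcpp.h>
using namespace Rcpp;

// Flat forest representation produced by .flattenForest() on the R side:
//   nTrees      int
//   left, right IntegerVector lists (per tree, 0-based child node ids, 0 = none)
//   splitVar    IntegerVector lists (per tree, 0-based feature column)
//   splitVal    NumericVector lists (per tree; split threshold at internal nodes)
//   predLevel   IntegerVector lists (per tree; 1-based class level at terminals)
// Split rule (ranger convention): x <= splitVal -> left child.

namespace {

struct Tree {
  const int *left, *right, *var, *pred;
  const double *val;
};

inline Tree get_tree(const List &left, const List &right, const List &svar,
                     const List &sval, const List &pred, int t) {
  Tree tr;
  tr.left = INTEGER(VECTOR_ELT(left, t));
  tr.right = INTEGER(VECTOR_ELT(right, t));
  tr.var = INTEGER(VECTOR_ELT(svar, t));
  tr.val = REAL(VECTOR_ELT(sval, t));
  tr.pred = INTEGER(VECTOR_ELT(pred, t));
  return tr;
}

// Traverse one tree for sample row i of X; feature `swapFeat` (0-based, or -1)
// is read from `swapVal` instead of X.
inline int traverse(const Tree &tr, const NumericMatrix &X, int i,
                    int swapFeat, double swapVal) {
  int node = 0;
  while (tr.left[node] != 0 || tr.right[node] != 0) {
    int v = tr.var[node];
    double x = (v == swapFeat) ? swapVal : X(i, v);
    node = (x <= tr.val[node]) ? tr.left[node] : tr.right[node];
  }
  return tr.pred[node];
}

// majority vote over per-class counts; tie -> smallest level index
inline int majority(const int *votes, int K) {
  int best = 0;
  for (int k = 1; k < K; ++k)
    if (votes[k] > votes[best]) best = k;
  return best + 1;
}

} // namespace

// Per-tree predictions for all samples: n x nTrees matrix of 1-based levels.
// [[Rcpp::export(name = ".cppForestPredict")]]
IntegerMatrix cpp_forest_predict(List forest, NumericMatrix X) {
  int nTrees = as<int>(forest["nTrees"]);
  List left = forest["left"], right = forest["right"],
       svar = forest["splitVar"], sval = forest["splitVal"],
       pred = forest["predLevel"];
  int n = X.nrow();
  IntegerMatrix out(n, nTrees);
  for (int t = 0; t < nTrees; ++t) {
    Tree tr = get_tree(left, right, svar, sval, pred, t);
    for (int i = 0; i < n; ++i) out(i, t) = traverse(tr, X, i, -1, 0.0);
  }
  return out;
}

// Out-of-bag permutation importance (Breiman): for each feature f and
// permutation repeat, the per-tree OOB accuracy drop caused by permuting f
// is averaged over all trees (trees that do not split on f contribute 0).
//   y      1-based true levels, length n
//   inbag  n x nTrees bootstrap counts (0 = sample is OOB for that tree)
//   perms  n x nRepeats permutation index matrix (1-based), shared by features
// Returns list(baseAcc = forest-level majority-vote OOB accuracy,
//              importance = M x nRepeats matrix of mean per-tree drops,
//              treesUsing = per-feature number of trees splitting on it).
// [[Rcpp::export(name = ".cppPermImportance")]]
List cpp_perm_importance(List forest, NumericMatrix X, IntegerVector y,
                         IntegerMatrix inbag, IntegerMatrix perms, int nLevels) {
  int nTrees = as<int>(forest["nTrees"]);
  List left = forest["left"], right = forest["right"],
       svar = forest["splitVar"], sval = forest["splitVal"],
       pred = forest["predLevel"];
  int n = X.nrow(), M = X.ncol(), nRep = perms.ncol(), K = nLevels;

  // baseline per-tree predictions and per-tree OOB sample lists
  IntegerMatrix P(n, nTrees);
  std::vector<std::vector<int> > treesUsing(M), oobList(nTrees);
  for (int t = 0; t < nTrees; ++t) {
    Tree tr = get_tree(left, right, svar, sval, pred, t);
    for (int i = 0; i < n; ++i) {
      P(i, t) = traverse(tr, X, i, -1, 0.0);
      if (inbag(i, t) == 0) oobList[t].push_back(i);
    }
    // record which features the tree splits on (internal nodes only)
    int nNodes = LENGTH(VECTOR_ELT(svar, t));
    std::vector<bool> seen(M, false);
    for (int nd = 0; nd < nNodes; ++nd) {
      if (tr.left[nd] != 0 || tr.right[nd] != 0) {
        int v = tr.var[nd];
        if (!seen[v]) { seen[v] = true; treesUsing[v].push_back(t); }
      }
    }
  }

  // baseline: per-tree OOB correct counts, and the forest-level
  // majority-vote OOB accuracy (samples with no OOB tree are skipped)
  std::vector<int> votes(n * K, 0);
  std::vector<int> nOobTree(nTrees, 0), nOobSample(n, 0), c0(nTrees, 0);
  for (int t = 0; t < nTrees; ++t)
    for (size_t oi = 0; oi < oobList[t].size(); ++oi) {
      int i = oobList[t][oi];
      votes[i * K + P(i, t) - 1]++;
      nOobSample[i]++;
      nOobTree[t]++;
      if (P(i, t) == y[i]) c0[t]++;
    }
  int nEval = 0, nCorrect = 0;
  for (int i = 0; i < n; ++i)
    if (nOobSample[i] > 0) {
      ++nEval;
      if (majority(&votes[i * K], K) == y[i]) ++nCorrect;
    }
  if (nEval == 0) stop("no out-of-bag samples; cannot compute OOB accuracy");
  double baseAcc = (double)nCorrect / nEval;

  // imp: mean per-tree drop; impSq: sum of squared per-tree drops (for
  // the across-tree standard error of the importance)
  NumericMatrix imp(M, nRep), impSq(M, nRep);
  for (int f = 0; f < M; ++f) {
    if (treesUsing[f].empty()) continue; // importance exactly 0
    for (int r = 0; r < nRep; ++r) {
      double drop = 0.0, dropSq = 0.0;
      for (size_t ti = 0; ti < treesUsing[f].size(); ++ti) {
        int t = treesUsing[f][ti];
        if (nOobTree[t] == 0) continue;
        Tree tr = get_tree(left, right, svar, sval, pred, t);
        int c1 = 0;
        for (size_t oi = 0; oi < oobList[t].size(); ++oi) {
          int i = oobList[t][oi];
          double xperm = X(perms(i, r) - 1, f);
          if (traverse(tr, X, i, f, xperm) == y[i]) ++c1;
        }
        double d = (double)(c0[t] - c1) / nOobTree[t];
        drop += d;
        dropSq += d * d;
      }
      imp(f, r) = drop / nTrees;
      impSq(f, r) = dropSq;
    }
  }
  IntegerVector nUsing(M);
  for (int f = 0; f < M; ++f) nUsing[f] = (int)treesUsing[f].size();
  return List::create(_["baseAcc"] = baseAcc, _["importance"] = imp,
                      _["importanceSq"] = impSq,
                      _["treesUsing"] = nUsing);
}
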