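#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exact branch-and-bound for the cardinality-constrained binary quadratic
// program behind the relatedness-penalized selection index:
//
//   max_x  sum_i d_i x_i - sum_{i<j} P_ij x_i x_j
//   s.t.   sum_i x_i = s,   Ycon x >= l,   x in {0,1}^n
//
// where d_i folds the linear merit and the diagonal of the penalty
// (x_i^2 = x_i) and P_ij = 2k G_ij carries the symmetric off-diagonal
// penalty. Candidates are explored in decreasing d order, include-first,
// so the first leaf is the unconstrained top-s set — already a strong
// incumbent. The node bound adds, for each free candidate, its best-case
// pair contribution against the (r-1) smallest remaining penalties; this
// never underestimates the subtree optimum, so pruning is admissible and
// the search is exact. Ties within tie_tol resolve to the
// lexicographically smallest original index set.

namespace {

struct BBState {
  int n, s, ncon;
  double feas_tol, tie_tol;
  std::vector<double> d;              // reordered
  std::vector<std::vector<double> > P;  // reordered, n x n
  std::vector<std::vector<double> > Ycon; // ncon x n, reordered
  std::vector<double> l;
  std::vector<int> orig;              // reordered position -> original index

  std::vector<int> chosen;            // reordered positions currently in
  std::vector<double> adj;            // adj[i] = sum_{j in chosen} P[i][j]
  std::vector<double> conSum;
  double curVal;

  bool haveBest;
  double bestVal;
  std::vector<int> bestSet;           // original indices, sorted
  long long nodes;
  long long nodeLimit;
  bool hitLimit;
};

bool lexSmaller(const std::vector<int>& a, const std::vector<int>& b) {
  return std::lexicographical_compare(a.begin(), a.end(), b.begin(), b.end());
}

void consider_leaf(BBState& st) {
  for (int t = 0; t < st.ncon; ++t)
    if (st.conSum[t] < st.l[t] - st.feas_tol) return;
  std::vector<int> set;
  set.reserve(st.chosen.size());
  for (size_t i = 0; i < st.chosen.size(); ++i) set.push_back(st.orig[st.chosen[i]]);
  std::sort(set.begin(), set.end());
  if (!st.haveBest || st.curVal > st.bestVal + st.tie_tol ||
      (std::fabs(st.curVal - st.bestVal) <= st.tie_tol && lexSmaller(set, st.bestSet))) {
    st.haveBest = true;
    if (st.curVal > st.bestVal) st.bestVal = st.curVal;
    st.bestSet = set;
  }
}

void dfs(BBState& st, int pos, int r) {
  if (st.hitLimit) return;
  if (++st.nodes > st.nodeLimit) { st.hitLimit = true; return; }
  if (r == 0) { consider_leaf(st); return; }
  int rem = st.n - pos;
  if (rem < r) return;

  // constraint reachability: even the r largest remaining scores fall short
  std::vector<double> buf;
  for (int t = 0; t < st.ncon; ++t) {
    buf.assign(st.Ycon[t].begin() + pos, st.Ycon[t].end());
    std::nth_element(buf.begin(), buf.begin() + (r - 1), buf.end(),
                     std::greater<double>());
    double top = 0.0;
    for (int q = 0; q < r; ++q) top += buf[q];
    if (st.conSum[t] + top < st.l[t] - st.feas_tol) return;
  }

  // objective bound
  if (st.haveBest) {
    std::vector<double> cand(rem);
    std::vector<double> prow;
    for (int i = pos; i < st.n; ++i) {
      double g = st.d[i] - st.adj[i];
      double pairUB = 0.0;
      if (r >= 2) {
        prow.clear();
        for (int j = pos; j < st.n; ++j)
          if (j != i) prow.push_back(st.P[i][j]);
        std::nth_element(prow.begin(), prow.begin() + (r - 2), prow.end());
        double small = 0.0;
        for (int q = 0; q < r - 1; ++q) small += prow[q];
        pairUB = -0.5 * small;
      }
      cand[i - pos] = g + pairUB;
    }
    std::nth_element(cand.begin(), cand.begin() + (r - 1), cand.end(),
                     std::greater<double>());
    double ub = st.curVal;
    for (int q = 0; q < r; ++q) ub += cand[q];
    if (ub < st.bestVal - st.tie_tol) return;
  }

  int i = pos;
  // include i
  double gain = st.d[i] - st.adj[i];
  st.curVal += gain;
  st.chosen.push_back(i);
  for (int j = pos + 1; j < st.n; ++j) st.adj[j] += st.P[i][j];
  for (int t = 0; t < st.ncon; ++t) st.conSum[t] += st.Ycon[t][i];
  dfs(st, pos + 1, r - 1);
  for (int t = 0; t < st.ncon; ++t) st.conSum[t] -= st.Ycon[t][i];
  for (int j = pos + 1; j < st.n; ++j) st.adj[j] -= st.P[i][j];
  st.chosen.pop_back();
  st.curVal -= gain;
  // exclude i
  dfs(st, pos + 1, r);
}

} // namespace

// [[Rcpp::export(name = ".bb_select_cpp")]]
List bb_select_cpp(NumericVector d, NumericMatrix P, NumericMatrix Ycon,
                   NumericVector l, int s, double feas_tol = 1e-6,
                   double tie_tol = 1e-9, double node_limit = 1e12) {
  int n = d.size();
  BBState st;
  st.n = n; st.s = s; st.ncon = Ycon.nrow();
  st.feas_tol = feas_tol; st.tie_tol = tie_tol;
  st.nodes = 0; st.nodeLimit = (long long) node_limit; st.hitLimit = false;
  st.haveBest = false; st.bestVal = -std::numeric_limits<double>::infinity();

  // order candidates by decreasing linear coefficient (stable for ties)
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return d[a] > d[b]; });
  st.orig = ord;
  st.d.resize(n);
  st.P.assign(n, std::vector<double>(n));
  st.Ycon.assign(st.ncon, std::vector<double>(n));
  st.l.assign(l.begin(), l.end());
  for (int i = 0; i < n; ++i) {
    st.d[i] = d[ord[i]];
    for (int j = 0; j < n; ++j) st.P[i][j] = P(ord[i], ord[j]);
    for (int t = 0; t < st.ncon; ++t) st.Ycon[t][i] = Ycon(t, ord[i]);
  }
  st.adj.assign(n, 0.0);
  st.conSum.assign(st.ncon, 0.0);
  st.curVal = 0.0;

  dfs(st, 0, s);

  IntegerVector idx;
  std::string status;
  double obj = NA_REAL;
  if (st.hitLimit && !st.haveBest) {
    status = "time_limit";
  } else if (!st.haveBest) {
    status = "infeasible";
  } else {
    status = st.hitLimit ? "time_limit" : "optimal";
    idx = IntegerVector(st.bestSet.begin(), st.bestSet.end());
    for (int q = 0; q < idx.size(); ++q) idx[q] += 1; // 1-based
    obj = st.bestVal;
  }
  return List::create(_["idx"] = idx, _["objective"] = obj,
                      _["status"] = status,
                      _["nodes"] = (double) st.nodes);
}
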