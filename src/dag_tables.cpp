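// Exhaustive labeled-DAG tables and BIC scoring for small variable subsets.
//
// The Bayesian reliability machinery averages over every DAG on a subset of
// at most five variables (29,281 DAGs at five nodes), so enumeration and
// per-DAG scoring are the hot path.  Enumeration is recursive over the
// ordered node pairs with reachability pruning, so cyclic branches are cut
// before completion instead of filtering all 2^(k(k-1)) digraphs.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct EnumState {
  int k;
  std::vector<std::pair<int, int>> pairs;  // ordered (u, v) candidate edges
  std::vector<int> reach;                  // reach[u]: bitmask reachable from u (incl. u)
  std::vector<int> parents;                // parents[v]: bitmask of parents of v
  // output accumulators
  std::vector<int> parent_masks;           // nDag * k
  std::vector<int> n_edges;
  std::vector<int> anc;                    // nDag * k * k row-major (i ancestor of j)
  std::vector<int> moral;                  // nDag * k * k moral adjacency
};

void emit(EnumState &st) {
  const int k = st.k;
  int ne = 0;
  for (int v = 0; v < k; ++v) {
    st.parent_masks.push_back(st.parents[v]);
    for (int u = 0; u < k; ++u)
      if (st.parents[v] & (1 << u)) ++ne;
  }
  st.n_edges.push_back(ne);
  // ancestor matrix from reach (strip self)
  for (int i = 0; i < k; ++i)
    for (int j = 0; j < k; ++j)
      st.anc.push_back(i != j && (st.reach[i] & (1 << j)) ? 1 : 0);
  // moral adjacency: parent-child plus co-parents of a common child
  std::vector<int> m(k * k, 0);
  for (int v = 0; v < k; ++v) {
    int pm = st.parents[v];
    for (int u = 0; u < k; ++u) {
      if (!(pm & (1 << u))) continue;
      m[u * k + v] = m[v * k + u] = 1;
      for (int w = u + 1; w < k; ++w)
        if (pm & (1 << w)) m[u * k + w] = m[w * k + u] = 1;
    }
  }
  st.moral.insert(st.moral.end(), m.begin(), m.end());
}

void recurse(EnumState &st, size_t idx) {
  if (idx == st.pairs.size()) {
    emit(st);
    return;
  }
  // branch 1: omit this edge
  recurse(st, idx + 1);
  // branch 2: add u -> v unless v already reaches u (would close a cycle)
  const int u = st.pairs[idx].first, v = st.pairs[idx].second;
  if (st.reach[v] & (1 << u)) return;
  std::vector<int> reach_save = st.reach;
  st.parents[v] |= (1 << u);
  for (int w = 0; w < st.k; ++w)
    if (st.reach[w] & (1 << u)) st.reach[w] |= st.reach[v];
  recurse(st, idx + 1);
  st.parents[v] &= ~(1 << u);
  st.reach = reach_save;
}

}  // namespace

// Enumerate every labeled DAG on k nodes (1 <= k <= 5) together with the
// per-DAG summaries used downstream: parent bitmasks, edge counts, ancestor
// indicators for every ordered pair, and "independent given all the rest"
// indicators for every unordered pair (non-adjacency in the moral graph).
// [[Rcpp::export]]
List cmx_dag_tables(int k) {
  if (k < 1 || k > 6) stop("subset size must be between 1 and 6");
  EnumState st;
  st.k = k;
  st.reach.assign(k, 0);
  for (int i = 0; i < k; ++i) st.reach[i] = 1 << i;
  st.parents.assign(k, 0);
  for (int u = 0; u < k; ++u)
    for (int v = 0; v < k; ++v)
      if (u != v) st.pairs.push_back(std::make_pair(u, v));
  recurse(st, 0);

  const int n = (int)st.n_edges.size();
  IntegerMatrix parent_mask(n, k);
  for (int d = 0; d < n; ++d)
    for (int j = 0; j < k; ++j)
      parent_mask(d, j) = st.parent_masks[(size_t)d * k + j];
  IntegerVector n_edges(st.n_edges.begin(), st.n_edges.end());

  const int np = k * (k - 1) / 2;
  LogicalMatrix dsep_rest(n, std::max(np, 1));
  LogicalMatrix ancestor(n, std::max(k * (k - 1), 1));
  for (int d = 0; d < n; ++d) {
    int p = 0, q = 0;
    for (int i = 0; i < k; ++i)
      for (int j = 0; j < k; ++j) {
        if (i < j) dsep_rest(d, p++) = st.moral[(size_t)d * k * k + i * k + j] == 0;
        if (i != j) ancestor(d, q++) = st.anc[(size_t)d * k * k + i * k + j] == 1;
      }
  }
  return List::create(_["k"] = k,
                      _["n_dags"] = n,
                      _["parent_mask"] = parent_mask,
                      _["n_edges"] = n_edges,
                      _["dsep_rest"] = dsep_rest,
                      _["ancestor"] = ancestor);
}

// Log-determinants of every principal submatrix of a correlation matrix,
// indexed by bitmask (mask 0 -> 0).  Errors on non-positive determinants so
// callers can advise a positive-definite projection.
// [[Rcpp::export]]
arma::vec cmx_subset_logdets(const arma::mat &corr) {
  const int k = corr.n_rows;
  const int nmask = 1 << k;
  arma::vec out(nmask, arma::fill::zeros);
  for (int mask = 1; mask < nmask; ++mask) {
    arma::uvec idx(__builtin_popcount(mask));
    int p = 0;
    for (int i = 0; i < k; ++i)
      if (mask & (1 << i)) idx(p++) = i;
    arma::mat sub = corr.submat(idx, idx);
    double val, sign;
    arma::log_det(val, sign, sub);
    if (sign <= 0 || !std::isfinite(val))
      stop("singular correlation submatrix; project to positive definite first");
    out(mask) = val;
  }
  return out;
}

// BIC log-scores for every DAG in a table: M * sum_i I(X_i, Pa_i) minus
// (log M / 2) * |edges|, with I from the Gaussian determinant identity.
// [[Rcpp::export]]
NumericVector cmx_dag_bic(const arma::mat &corr, double M,
                          const IntegerMatrix &parent_mask,
                          const IntegerVector &n_edges) {
  const int k = corr.n_rows;
  arma::vec ld = cmx_subset_logdets(corr);
  // local contribution ls[mask][j] = M * I(X_j, X_mask)
  std::vector<double> ls((size_t)(1 << k) * k, 0.0);
  for (int j = 0; j < k; ++j)
    for (int mask = 0; mask < (1 << k); ++mask) {
      if (mask & (1 << j)) continue;
      double mi = -0.5 * (ld(mask | (1 << j)) - ld(mask) - ld(1 << j));
      ls[(size_t)mask * k + j] = M * mi;
    }
  const int n = parent_mask.nrow();
  const double pen = 0.5 * std::log(M);
  NumericVector out(n);
  for (int d = 0; d < n; ++d) {
    double s = 0.0;
    for (int j = 0; j < k; ++j) s += ls[(size_t)parent_mask(d, j) * k + j];
    out[d] = s - pen * n_edges[d];
  }
  return out;
}
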