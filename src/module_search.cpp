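#include <Rcpp.h>
#include <chrono>
using namespace Rcpp;

// Exact search for the connected, density-constrained gene set of size k
// maximizing the exclusivity-penalized phenotype-coverage objective
//
//   sum_{j: c_j >= 1} w_j  -  lambda * sum_j max(0, c_j - 1) * |w_j|
//
// where c_j is the number of selected genes altered in patient j.
//
// Connected induced subgraphs are enumerated exactly once with the standard
// rooted-extension scheme (ESU): a subgraph is grown only from its
// minimum-index vertex, and a vertex enters the extension set only when first
// reached. Partial sets are pruned with the admissible bound
//   current score + sum of positive w over still-uncovered patients,
// which dominates every completion because added genes can only add coverage
// (uncovered j contributes at most max(w_j, 0)) and can only deepen the
// exclusivity penalty on already-covered patients.

namespace {

struct Search {
  int n, m, k;
  double density_min, lambda;
  const IntegerMatrix &alt;             // n genes x m patients, 0/1
  const std::vector<std::vector<int>> &adj;
  std::vector<int> S;                   // current set
  std::vector<int> cov;                 // per-patient coverage count
  std::vector<int> in_S;                // 0/1 membership
  double score;                         // objective of S
  double pos_uncovered;                 // sum of positive w over uncovered
  int edges_in;                         // edges inside S
  const NumericVector &w;
  const NumericVector &absw;
  std::vector<int> best;
  double best_obj;
  bool have_best;
  long long n_leaves;
  bool timed_out;
  std::chrono::steady_clock::time_point deadline;
  long long tick;

  Search(const IntegerMatrix &alt_, const std::vector<std::vector<int>> &adj_,
         const NumericVector &w_, const NumericVector &absw_, int k_,
         double density_min_, double lambda_, double time_limit)
      : n(alt_.nrow()), m(alt_.ncol()), k(k_), density_min(density_min_),
        lambda(lambda_), alt(alt_), adj(adj_), cov(m, 0), in_S(n, 0),
        score(0.0), pos_uncovered(0.0), edges_in(0), w(w_), absw(absw_),
        best_obj(R_NegInf), have_best(false), n_leaves(0), timed_out(false),
        tick(0) {
    for (int j = 0; j < m; ++j)
      if (w[j] > 0) pos_uncovered += w[j];
    deadline = std::chrono::steady_clock::now() +
               std::chrono::duration_cast<std::chrono::steady_clock::duration>(
                   std::chrono::duration<double>(time_limit));
  }

  bool out_of_time() {
    if (timed_out) return true;
    if ((++tick & 2047) == 0 &&
        std::chrono::steady_clock::now() > deadline)
      timed_out = true;
    return timed_out;
  }

  void add_gene(int g) {
    S.push_back(g);
    in_S[g] = 1;
    for (int v : adj[g]) edges_in += in_S[v];
    // in_S[g] already 1 but g not in adj[g] (no self-loops)
    for (int j = 0; j < m; ++j) {
      if (alt(g, j)) {
        if (cov[j] == 0) {
          score += w[j];
          if (w[j] > 0) pos_uncovered -= w[j];
        } else {
          score -= lambda * absw[j];
        }
        ++cov[j];
      }
    }
  }

  void remove_gene(int g) {
    for (int j = 0; j < m; ++j) {
      if (alt(g, j)) {
        --cov[j];
        if (cov[j] == 0) {
          score -= w[j];
          if (w[j] > 0) pos_uncovered += w[j];
        } else {
          score += lambda * absw[j];
        }
      }
    }
    in_S[g] = 0;
    for (int v : adj[g]) edges_in -= in_S[v];
    S.pop_back();
  }

  // lexicographic comparison of sorted index sets
  bool lex_smaller(const std::vector<int> &a, const std::vector<int> &b) {
    std::vector<int> sa(a), sb(b);
    std::sort(sa.begin(), sa.end());
    std::sort(sb.begin(), sb.end());
    return sa < sb;
  }

  void consider_leaf() {
    ++n_leaves;
    double denom = (k > 1) ? k * (k - 1) / 2.0 : 1.0;
    double dens = (k > 1) ? edges_in / denom : 1.0;
    if (dens + 1e-12 < density_min) return;
    if (!have_best || score > best_obj + 1e-12 ||
        (score > best_obj - 1e-12 && lex_smaller(S, best))) {
      best = S;
      best_obj = score;
      have_best = true;
    }
  }

  void extend(std::vector<int> ext, int root, std::vector<int> &seen) {
    if (out_of_time()) return;
    if ((int)S.size() == k) {
      consider_leaf();
      return;
    }
    // admissible bound: completions can only add positive uncovered weight
    if (have_best && score + pos_uncovered < best_obj - 1e-12) return;
    while (!ext.empty()) {
      int g = ext.back();
      ext.pop_back();
      std::vector<int> ext2 = ext;
      std::vector<int> newly;
      for (int v : adj[g]) {
        if (v > root && !in_S[v] && !seen[v]) {
          seen[v] = 1;
          newly.push_back(v);
          ext2.push_back(v);
        }
      }
      add_gene(g);
      extend(ext2, root, seen);
      remove_gene(g);
      for (int v : newly) seen[v] = 0;
      if (timed_out) return;
    }
  }

  void run() {
    std::vector<int> seen(n, 0);
    for (int root = 0; root < n && !timed_out; ++root) {
      if (k == 1) {
        add_gene(root);
        consider_leaf();
        remove_gene(root);
        continue;
      }
      std::vector<int> ext;
      seen[root] = 1;
      for (int v : adj[root])
        if (v > root) {
          seen[v] = 1;
          ext.push_back(v);
        }
      add_gene(root);
      extend(ext, root, seen);
      remove_gene(root);
      seen[root] = 0;
      for (int v : adj[root])
        if (v > root) seen[v] = 0;
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".module_search_cpp")]]
List module_search_cpp(IntegerMatrix alt, List adjacency, NumericVector w,
                       int k, double density_min, double lambda,
                       double time_limit) {
  int n = alt.nrow();
  std::vector<std::vector<int>> adj(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector nb = adjacency[i];
    adj[i] = std::vector<int>(nb.begin(), nb.end());
  }
  NumericVector absw = abs(w);
  Search s(alt, adj, w, absw, k, density_min, lambda, time_limit);
  s.run();
  if (!s.have_best)
    return List::create(_["feasible"] = false,
                        _["proven_optimal"] = !s.timed_out,
                        _["n_candidates"] = (double)s.n_leaves);
  std::sort(s.best.begin(), s.best.end());
  return List::create(_["feasible"] = true,
                      _["genes"] = IntegerVector(s.best.begin(), s.best.end()),
                      _["objective"] = s.best_obj,
                      _["proven_optimal"] = !s.timed_out,
                      _["n_candidates"] = (double)s.n_leaves);
}
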