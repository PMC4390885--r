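#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Nodes of the family subtree T_m are supplied in postorder (every child
// before its parent; the subtree root is the last element). parent[i] is
// the position of i's parent in the same array, -1 for the subtree root.
// leafcount[i] >= 0 for leaves (the observed paralog count), -1 for
// interior nodes. The per-edge cost of changing the copy number from k
// (parent) to j (child u) is
//   dup_w * node_w[u] * (j - k)   if j > k   (duplications)
//   loss_w * node_w[u] * (k - j)  if j < k   (losses)
// which reduces to |k - j| under the default unit weights.

static inline double edge_cost(int k_parent, int j_child, double dupw,
                               double lossw, double nw) {
  if (j_child > k_parent) return dupw * nw * (j_child - k_parent);
  if (j_child < k_parent) return lossw * nw * (k_parent - j_child);
  return 0.0;
}

// subtree maxima P_v: max observed count over the leaves below v
static std::vector<int> subtree_max(const IntegerVector& parent,
                                    const IntegerVector& leafcount) {
  int n = parent.size();
  std::vector<int> P(n, 0);
  for (int i = 0; i < n; ++i)
    if (leafcount[i] >= 0) P[i] = leafcount[i];
  for (int i = 0; i < n; ++i)
    if (parent[i] >= 0 && P[i] > P[parent[i]]) P[parent[i]] = P[i];
  return P;
}

// [[Rcpp::export(name = ".dollo_dp")]]
List dollo_dp(IntegerVector parent, IntegerVector leafcount, int kmax,
              double dupw, double lossw, NumericVector nodew) {
  const double INF = std::numeric_limits<double>::infinity();
  int n = parent.size();
  std::vector<int> P = subtree_max(parent, leafcount);
  int Pm = P[n - 1];
  int K = kmax >= Pm ? kmax : Pm;  // DP range 0..K; K = P_m by default

  // S[i][k]: parsimony score of the subtree below node i given i holds k
  // copies; N[i][k]: number of optimal assignments of that subtree.
  std::vector<std::vector<double> > S(n, std::vector<double>(K + 1, 0.0));
  std::vector<std::vector<double> > N(n, std::vector<double>(K + 1, 1.0));

  for (int i = 0; i < n; ++i) {
    if (leafcount[i] >= 0) {                    // leaf: fixed by the data
      for (int k = 0; k <= K; ++k) {
        S[i][k] = (k == leafcount[i]) ? 0.0 : INF;
        N[i][k] = (k == leafcount[i]) ? 1.0 : 0.0;
      }
    } else {
      // Dollo constraint: zero copies are infeasible wherever the family
      // is recorded somewhere below
      S[i][0] = (P[i] == 0) ? 0.0 : INF;
      N[i][0] = (P[i] == 0) ? 1.0 : 0.0;
    }
  }

  // bottom-up fill; children of v all precede v, so a single pass works;
  // each child's contribution is minimised independently
  for (int i = 0; i < n; ++i) {
    int p = parent[i];
    if (p < 0) continue;
    for (int k = 0; k <= K; ++k) {
      if (leafcount[p] >= 0) continue;         // leaves have no children
      if (!std::isfinite(S[p][k])) continue;   // k=0 with P>=1 stays INF
      if (k == 0 && P[p] >= 1) continue;
      double best = INF, nopt = 0.0;
      for (int j = 0; j <= K; ++j) {
        if (!std::isfinite(S[i][j])) continue;
        double c = S[i][j] + edge_cost(k, j, dupw, lossw, nodew[i]);
        if (c < best - 1e-9) { best = c; nopt = N[i][j]; }
        else if (c <= best + 1e-9) { nopt += N[i][j]; }
      }
      S[p][k] += best;
      N[p][k] *= nopt;
    }
  }

  // root of T_m: score S = min_k S_km, ties broken by the smallest count
  int m = n - 1;
  double S_opt = INF, n_opt = 0.0;
  int k_root = 0;
  for (int k = 0; k <= K; ++k) {
    if (S[m][k] < S_opt - 1e-9) { S_opt = S[m][k]; k_root = k; n_opt = 0.0; }
    if (std::isfinite(S[m][k]) && S[m][k] <= S_opt + 1e-9) n_opt += N[m][k];
  }

  // backtrace, parents before children (reverse postorder); per child,
  // the smallest j attaining min_j S_ju + delta(j, k_parent)
  std::vector<int> assign(n, 0);
  assign[m] = k_root;
  for (int i = n - 2; i >= 0; --i) {
    int kp = assign[parent[i]];
    double best = INF;
    int bj = 0;
    for (int j = 0; j <= K; ++j) {
      if (!std::isfinite(S[i][j])) continue;
      double c = S[i][j] + edge_cost(kp, j, dupw, lossw, nodew[i]);
      if (c < best - 1e-9) { best = c; bj = j; }
    }
    assign[i] = bj;
  }

  // independent check: total cost of the returned assignment
  double total = 0.0;
  for (int i = 0; i < n; ++i)
    if (parent[i] >= 0)
      total += edge_cost(assign[parent[i]], assign[i], dupw, lossw, nodew[i]);

  return List::create(_["score"] = S_opt,
                      _["counts"] = IntegerVector(assign.begin(), assign.end()),
                      _["n_optima"] = n_opt,
                      _["P"] = IntegerVector(P.begin(), P.end()),
                      _["assigned_cost"] = total);
}

// Exhaustive reference: enumerate every Dollo-feasible interior assignment
// with counts in 0..P_m (0 allowed only where no copy is observed below)
// and take the minimum summed edge cost. Deliberately shares nothing with
// the dynamic program above; used as the independent oracle in tests.
// [[Rcpp::export(name = ".dollo_enum")]]
List dollo_enum(IntegerVector parent, IntegerVector leafcount,
                double dupw, double lossw, NumericVector nodew) {
  int n = parent.size();
  std::vector<int> P = subtree_max(parent, leafcount);
  int Pm = P[n - 1];

  std::vector<int> interior;
  for (int i = 0; i < n; ++i)
    if (leafcount[i] < 0) interior.push_back(i);
  int ni = interior.size();

  std::vector<int> cnt(n, 0);
  for (int i = 0; i < n; ++i)
    if (leafcount[i] >= 0) cnt[i] = leafcount[i];

  std::vector<int> lo(ni), hi(ni), cur(ni);
  for (int t = 0; t < ni; ++t) {
    lo[t] = (P[interior[t]] == 0) ? 0 : 1;
    hi[t] = Pm;
    cur[t] = lo[t];
  }

  double best = std::numeric_limits<double>::infinity();
  double nbest = 0.0;
  std::vector<int> argmin(n, 0);
  bool done = false;
  while (!done) {
    for (int t = 0; t < ni; ++t) cnt[interior[t]] = cur[t];
    double tot = 0.0;
    for (int i = 0; i < n; ++i)
      if (parent[i] >= 0)
        tot += edge_cost(cnt[parent[i]], cnt[i], dupw, lossw, nodew[i]);
    if (tot < best - 1e-9) { best = tot; nbest = 1.0; argmin = cnt; }
    else if (tot <= best + 1e-9) { nbest += 1.0; }
    // odometer increment
    if (ni == 0) break;
    int t = 0;
    while (t < ni) {
      if (cur[t] < hi[t]) { cur[t]++; break; }
      cur[t] = lo[t];
      ++t;
    }
    if (t == ni) done = true;
  }

  return List::create(_["score"] = best,
                      _["n_optima"] = nbest,
                      _["counts"] = IntegerVector(argmin.begin(), argmin.end()),
                      _["P"] = IntegerVector(P.begin(), P.end()));
}
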