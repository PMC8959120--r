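#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Inner loop of the adaptive-rewiring simulator.
//
// One epoch = `updates_per_rewiring` coupled logistic-map updates followed by
// one rewiring attempt.  The update is
//   x_i+ = 1 - alpha_i * [ (1-eps_i) x_i^2 + (eps_i/deg_i) sum_{j in B_i} x_j^2 ]
// (neighbor_amp = 0, receiving node's amplitude applied to the neighbor term),
// or, with each neighbor's own amplitude in the coupling sum (neighbor_amp = 1),
//   x_i+ = 1 - (1-eps_i) alpha_i x_i^2 - (eps_i/deg_i) sum_{j in B_i} alpha_j x_j^2.
//
// Because rewiring conserves the edge count, the graph is held in two
// fixed-length endpoint arrays iterated sequentially in the hot loop, plus a
// dense adjacency matrix for O(1) membership tests.  The endpoint arrays are
// kept sorted lexicographically, so for every node the neighbor
// contributions accumulate in ascending index order: the floating-point
// trajectory is a pure function of the initial state and the pivot draws,
// independent of how the run is cut into segments.
//
// The rewiring attempt picks a pivot uniformly at random (one unif_rand draw
// from R's RNG stream), disconnects it from its most activity-dissimilar
// neighbor and connects it to its most similar non-neighbor; argmax ties
// break at the lowest node index.  A pivot connected to all other nodes
// terminates the model (no non-neighbor exists); a node isolated by a
// previous rewiring terminates it at the next update (degree-zero division).
// Termination is absorbing: the state is returned frozen.

// [[Rcpp::export]]
List run_segment_cpp(IntegerMatrix adj, NumericVector act,
                     NumericVector alpha, NumericVector eps,
                     int n_attempts, int updates_per_rewiring,
                     int neighbor_amp) {
  const int n = adj.nrow();
  IntegerMatrix A = clone(adj);
  NumericVector x = clone(act);

  std::vector<int> eu, ev, deg(n, 0);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (A(i, j) != 0) {
        eu.push_back(i); ev.push_back(j);   // sorted lexicographically
        ++deg[i]; ++deg[j];
      }
  const int m = (int)eu.size();
  // position of edge (a, b), a < b, in the sorted endpoint arrays
  auto edge_pos = [&](int a, int b) {
    int lo = 0, hi = (int)eu.size();
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (eu[mid] < a || (eu[mid] == a && ev[mid] < b)) lo = mid + 1;
      else hi = mid;
    }
    return lo;
  };

  std::vector<double> w(n), S(n), xn(n);
  bool terminated = false;
  std::string reason = "none";
  int term_node = NA_INTEGER;
  int attempts_done = 0;
  double updates_done = 0;

  for (int att = 0; att < n_attempts && !terminated; ++att) {
    // dynamics phase
    for (int u = 0; u < updates_per_rewiring && !terminated; ++u) {
      if (neighbor_amp == 0)
        for (int j = 0; j < n; ++j) w[j] = x[j] * x[j];
      else
        for (int j = 0; j < n; ++j) w[j] = alpha[j] * x[j] * x[j];
      std::fill(S.begin(), S.end(), 0.0);
      for (int e = 0; e < m; ++e) {
        const int a = eu[e], b = ev[e];
        S[a] += w[b];
        S[b] += w[a];
      }
      for (int i = 0; i < n; ++i) {
        if (deg[i] == 0) {
          terminated = true; reason = "isolated_node"; term_node = i + 1;
          break;
        }
        if (neighbor_amp == 0)
          xn[i] = 1.0 - alpha[i] * ((1.0 - eps[i]) * w[i] + eps[i] * S[i] / deg[i]);
        else
          xn[i] = 1.0 - (1.0 - eps[i]) * w[i] - eps[i] * S[i] / deg[i];
      }
      if (terminated) break;
      for (int i = 0; i < n; ++i) x[i] = xn[i];
      updates_done += 1;
    }
    if (terminated) break;

    // rewiring attempt
    int pivot = (int)(unif_rand() * n);
    if (pivot >= n) pivot = n - 1;
    if (deg[pivot] == n - 1) {
      terminated = true; reason = "no_non_neighbor"; term_node = pivot + 1;
      break;
    }
    // most dissimilar neighbor (xi), most similar non-neighbor (zeta);
    // first index wins on ties
    int xi = -1, zeta = -1;
    double best_d = -1.0, best_s = -2.0;
    const double xp = x[pivot];
    for (int j = 0; j < n; ++j) {
      if (j == pivot) continue;
      double d = x[j] - xp; if (d < 0) d = -d;
      if (A(pivot, j) != 0) {
        if (d > best_d) { best_d = d; xi = j; }
      } else {
        double s = 1.0 - d;
        if (s > best_s) { best_s = s; zeta = j; }
      }
    }
    // replace edge (pivot, xi) by (pivot, zeta), keeping the arrays sorted
    {
      const int ra = pivot < xi ? pivot : xi, rb = pivot < xi ? xi : pivot;
      const int pos = edge_pos(ra, rb);
      eu.erase(eu.begin() + pos); ev.erase(ev.begin() + pos);
      const int aa = pivot < zeta ? pivot : zeta, ab = pivot < zeta ? zeta : pivot;
      const int ins = edge_pos(aa, ab);
      eu.insert(eu.begin() + ins, aa); ev.insert(ev.begin() + ins, ab);
    }
    A(pivot, xi) = 0; A(xi, pivot) = 0;
    A(pivot, zeta) = 1; A(zeta, pivot) = 1;
    --deg[xi]; ++deg[zeta];
    ++attempts_done;
  }

  return List::create(
    _["adjacency"] = A,
    _["activations"] = x,
    _["attempts_done"] = attempts_done,
    _["updates_done"] = updates_done,
    _["terminated"] = terminated,
    _["reason"] = reason,
    _["term_node"] = term_node);
}
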