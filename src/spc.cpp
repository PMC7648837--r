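#include <Rcpp.h>
using namespace Rcpp;

// Swendsen-Wang sweeps of a q-state Potts model on a sparse interaction
// graph, one run per temperature.  Edges are same-state bonded with
// probability 1 - exp(-J_ij / T); bonded components are then flipped to a
// common random state.  The returned matrix holds, per edge and per
// temperature, the fraction of post-burn-in sweeps in which the two end
// points shared a state (the point-point correlation used by
// superparamagnetic clustering).
//
// Uses R's RNG so set.seed() on the R side makes runs reproducible.
// [[Rcpp::export]]
NumericMatrix spc_sweep_cpp(IntegerVector edge_i, IntegerVector edge_j,
                            NumericVector J, NumericVector temperatures,
                            int n_points, int n_iter, int q, int n_burn) {
  const int m = edge_i.size();
  const int nT = temperatures.size();
  NumericMatrix corr(m, nT);
  std::vector<int> state(n_points), parent(n_points), rank_(n_points);
  RNGScope scope;

  for (int t = 0; t < nT; ++t) {
    const double T = temperatures[t];
    // Bond probabilities for this temperature; T = 0 bonds deterministically.
    std::vector<double> pbond(m);
    for (int e = 0; e < m; ++e)
      pbond[e] = (T <= 0.0) ? 1.0 : 1.0 - std::exp(-J[e] / T);

    for (int i = 0; i < n_points; ++i)
      state[i] = (int)(unif_rand() * q);
    int counted = 0;

    for (int it = 0; it < n_iter; ++it) {
      // union-find reset
      for (int i = 0; i < n_points; ++i) { parent[i] = i; rank_[i] = 0; }
      for (int e = 0; e < m; ++e) {
        const int a = edge_i[e], b = edge_j[e];
        if (state[a] == state[b] && unif_rand() < pbond[e]) {
          // union(a, b)
          int ra = a, rb = b;
          while (parent[ra] != ra) ra = parent[ra] = parent[parent[ra]];
          while (parent[rb] != rb) rb = parent[rb] = parent[parent[rb]];
          if (ra != rb) {
            if (rank_[ra] < rank_[rb]) std::swap(ra, rb);
            parent[rb] = ra;
            if (rank_[ra] == rank_[rb]) ++rank_[ra];
          }
        }
      }
      // one fresh random state per component
      std::vector<int> newstate(n_points, -1);
      for (int i = 0; i < n_points; ++i) {
        int r = i;
        while (parent[r] != r) r = parent[r] = parent[parent[r]];
        if (newstate[r] < 0) newstate[r] = (int)(unif_rand() * q);
        state[i] = newstate[r];
      }
      if (it >= n_burn) {
        ++counted;
        for (int e = 0; e < m; ++e)
          if (state[edge_i[e]] == state[edge_j[e]]) corr(e, t) += 1.0;
      }
    }
    if (counted > 0)
      for (int e = 0; e < m; ++e) corr(e, t) /= counted;
  }
  return corr;
}
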