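#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Two-phase adjacency-constrained complete-linkage agglomeration.
//
// Clusters are indexed by their smallest member bin (0-based internally);
// merging i < j keeps the cluster at slot i, so slot index == representative.
// Phase 1 only merges cluster pairs joined by at least one cross-cluster
// bin-adjacency edge; when no adjacent pair remains (each adjacency component
// has collapsed to one cluster) the remaining merges are standard complete
// linkage. Ties on distance break to the lexicographically smallest (a, b).
//
// Each cluster caches its best partner among larger-indexed active clusters;
// complete-linkage distances only grow under merging, so a cached partner is
// only re-scanned when it was involved in the last merge, while the merged
// cluster is offered as a new candidate to everyone else.

static const double INF = std::numeric_limits<double>::infinity();

struct NNState {
  std::vector<int> nn;
  std::vector<double> nndist;
};

static void recompute_nn(int k, int n, const std::vector<char> &active,
                         const std::vector<double> &D,
                         const std::vector<char> &A,
                         bool constrained, NNState &s) {
  int best = -1;
  double bestd = INF;
  for (int j = k + 1; j < n; ++j) {
    if (!active[j]) continue;
    if (constrained && !A[(size_t)k * n + j]) continue;
    double d = D[(size_t)k * n + j];
    if (d < bestd) { bestd = d; best = j; }
  }
  s.nn[k] = best;
  s.nndist[k] = bestd;
}

// [[Rcpp::export]]
NumericMatrix constrained_linkage_cpp(NumericMatrix D0, LogicalMatrix A0) {
  const int n = D0.nrow();
  NumericMatrix out(std::max(n - 1, 0), 4);
  if (n < 2) return out;

  std::vector<double> D((size_t)n * n);
  std::vector<char> A((size_t)n * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      D[(size_t)i * n + j] = D0(i, j);
      A[(size_t)i * n + j] = (char)(A0(i, j) != 0);
    }
  std::vector<char> active(n, 1);

  NNState s;
  s.nn.assign(n, -1);
  s.nndist.assign(n, INF);
  bool constrained = true;
  for (int k = 0; k < n; ++k) recompute_nn(k, n, active, D, A, constrained, s);

  for (int step = 0; step < n - 1; ++step) {
    // global best pair: smallest distance, then smallest (k, nn[k])
    int bi = -1;
    double bd = INF;
    for (int k = 0; k < n; ++k) {
      if (!active[k] || s.nn[k] < 0) continue;
      if (s.nndist[k] < bd) { bd = s.nndist[k]; bi = k; }
    }
    if (bi < 0 || bd == INF) {
      if (constrained) {
        constrained = false;  // phase switch: no adjacent pair remains
        for (int k = 0; k < n; ++k)
          if (active[k]) recompute_nn(k, n, active, D, A, constrained, s);
        --step;
        continue;
      }
      stop("internal error: no mergeable pair found");
    }
    const int i = bi, j = s.nn[bi];
    out(step, 0) = i + 1;
    out(step, 1) = j + 1;
    out(step, 2) = bd;
    out(step, 3) = constrained ? 1 : 2;

    active[j] = 0;
    for (int k = 0; k < n; ++k) {
      if (!active[k] || k == i) continue;
      double dj = D[(size_t)j * n + k];
      size_t ik = (size_t)i * n + k, ki = (size_t)k * n + i;
      if (dj > D[ik]) { D[ik] = dj; D[ki] = dj; }
      if (A[(size_t)j * n + k]) { A[ik] = 1; A[ki] = 1; }
    }
    recompute_nn(i, n, active, D, A, constrained, s);
    for (int k = 0; k < n; ++k) {
      if (!active[k] || k == i) continue;
      if (s.nn[k] == i || s.nn[k] == j) {
        recompute_nn(k, n, active, D, A, constrained, s);
      } else if (k < i) {
        if (!constrained || A[(size_t)k * n + i]) {
          double d = D[(size_t)k * n + i];
          if (d < s.nndist[k] || (d == s.nndist[k] && i < s.nn[k])) {
            s.nndist[k] = d;
            s.nn[k] = i;
          }
        }
      }
    }
  }
  return out;
}
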