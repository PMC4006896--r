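#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Full L1 cost: sum_ij | A[i][j] - B[p[i]][p[j]] | over the whole matrix.
static long full_cost(const IntegerMatrix &A, const IntegerMatrix &B,
                      const std::vector<int> &p) {
  const int n = A.nrow();
  long c = 0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      c += std::abs(A(i, j) - B(p[i], p[j]));
  return c;
}

// Cost restricted to entries whose row or column lies in {u, v};
// swapping positions u and v of p changes the cost only there.
static long local_cost(const IntegerMatrix &A, const IntegerMatrix &B,
                       const std::vector<int> &p, int u, int v) {
  const int n = A.nrow();
  long s = 0;
  for (int j = 0; j < n; ++j) {
    s += std::abs(A(u, j) - B(p[u], p[j]));
    s += std::abs(A(v, j) - B(p[v], p[j]));
  }
  for (int i = 0; i < n; ++i) {
    if (i == u || i == v) continue;
    s += std::abs(A(i, u) - B(p[i], p[u]));
    s += std::abs(A(i, v) - B(p[i], p[v]));
  }
  return s;
}

// Simulated-annealing alignment of B to A by node reordering.
// inits: matrix of 0-based starting permutations, one per row; restarts
// beyond nrow(inits) start from uniformly random permutations. The best
// cost ever visited (including every starting point) is returned, so the
// identity start guarantees cost <= cost(identity).
// [[Rcpp::export]]
List sa_align_cpp(IntegerMatrix A, IntegerMatrix B, IntegerMatrix inits,
                  int restarts, int sweeps, double cooling, int seed) {
  const int n = A.nrow();
  std::vector<int> best(n), p(n);
  long best_cost = -1;

  for (int r = 0; r < restarts; ++r) {
    std::mt19937 rng(static_cast<uint32_t>(seed) +
                     0x9e3779b9u * static_cast<uint32_t>(r + 1));
    auto unif = [&rng]() { return rng() / 4294967296.0; };

    if (r < inits.nrow()) {
      for (int i = 0; i < n; ++i) p[i] = inits(r, i);
    } else {
      for (int i = 0; i < n; ++i) p[i] = i;
      for (int i = n - 1; i > 0; --i) {   // Fisher-Yates
        int j = static_cast<int>(rng() % static_cast<uint32_t>(i + 1));
        std::swap(p[i], p[j]);
      }
    }

    long cost = full_cost(A, B, p);
    if (best_cost < 0 || cost < best_cost) { best_cost = cost; best = p; }
    if (best_cost == 0) break;
    if (n < 2) continue;

    const double T0 = std::max<long>(cost, 1) / std::log(2.0);
    double T = T0;

    for (int s = 0; s < sweeps; ++s) {
      for (int k = 0; k < n; ++k) {
        int u = static_cast<int>(rng() % static_cast<uint32_t>(n));
        int v = static_cast<int>(rng() % static_cast<uint32_t>(n - 1));
        if (v >= u) ++v;
        long before = local_cost(A, B, p, u, v);
        std::swap(p[u], p[v]);
        long after = local_cost(A, B, p, u, v);
        long delta = after - before;
        if (delta <= 0 || unif() < std::exp(-delta / T)) {
          cost += delta;
          if (cost < best_cost) { best_cost = cost; best = p; }
        } else {
          std::swap(p[u], p[v]);   // reject
        }
      }
      if (best_cost == 0 || T < 1e-4 * T0) break;
      T *= cooling;
    }
    if (best_cost == 0) break;
  }

  IntegerVector perm(n);
  for (int i = 0; i < n; ++i) perm[i] = best[i];
  return List::create(Named("perm") = perm,
                      Named("cost") = static_cast<double>(best_cost));
}

// Exhaustive minimum over all n! permutations (oracle for small n).
// Returns the lexicographically smallest optimal permutation.
// [[Rcpp::export]]
List exhaustive_align_cpp(IntegerMatrix A, IntegerMatrix B) {
  const int n = A.nrow();
  if (n > 9) stop("exhaustive search limited to n <= 9 nodes");
  std::vector<int> p(n), best(n);
  for (int i = 0; i < n; ++i) p[i] = i;
  best = p;
  long best_cost = full_cost(A, B, p);
  while (std::next_permutation(p.begin(), p.end())) {
    long c = full_cost(A, B, p);
    if (c < best_cost) { best_cost = c; best = p; }
  }
  IntegerVector perm(n);
  for (int i = 0; i < n; ++i) perm[i] = best[i];
  return List::create(Named("perm") = perm,
                      Named("cost") = static_cast<double>(best_cost));
}
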