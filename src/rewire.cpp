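#include <Rcpp.h>
#include <random>
#include <vector>

using namespace Rcpp;

// Maslov-Sneppen degree-preserving randomization by double-edge swaps.
// Two edges (a,b), (c,d) on four distinct vertices are replaced by
// (a,d), (c,b) when neither replacement already exists. target_swaps
// counts *accepted* swaps; the attempt budget caps pathological inputs
// (a complete graph admits no swap and is returned unchanged).
// [[Rcpp::export]]
IntegerMatrix rewire_ms_cpp(IntegerMatrix adj, double target_swaps, int seed,
                            double attempt_factor = 100.0) {
  const int n = adj.nrow();
  IntegerMatrix a = clone(adj);
  std::vector<std::pair<int, int> > edges;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (a(i, j)) edges.push_back(std::make_pair(i, j));

  const long m = static_cast<long>(edges.size());
  if (m < 2) return a;

  std::mt19937 rng(static_cast<uint32_t>(seed));
  long accepted = 0;
  const long target = static_cast<long>(target_swaps);
  long attempts = 0;
  const long max_attempts =
      std::max<long>(1000, static_cast<long>(attempt_factor * target_swaps));

  while (accepted < target && attempts < max_attempts) {
    ++attempts;
    long e1 = static_cast<long>(rng() % static_cast<uint32_t>(m));
    long e2 = static_cast<long>(rng() % static_cast<uint32_t>(m));
    if (e1 == e2) continue;
    int ea = edges[e1].first, eb = edges[e1].second;
    int c = edges[e2].first, d = edges[e2].second;
    if (rng() & 1u) std::swap(c, d);   // random orientation
    if (ea == c || ea == d || eb == c || eb == d) continue;
    if (a(ea, d) || a(c, eb)) continue;
    a(ea, eb) = a(eb, ea) = 0;
    a(c, d) = a(d, c) = 0;
    a(ea, d) = a(d, ea) = 1;
    a(c, eb) = a(eb, c) = 1;
    edges[e1] = std::make_pair(std::min(ea, d), std::max(ea, d));
    edges[e2] = std::make_pair(std::min(c, eb), std::max(c, eb));
    ++accepted;
  }
  return a;
}
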