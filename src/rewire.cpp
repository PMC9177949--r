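#include <Rcpp.h>
using namespace Rcpp;

// Degree-preserving double-edge swaps (Maslov-Sneppen) on a simple
// undirected 0/1 adjacency matrix. Proposals draw two distinct edges and a
// random pairing; a proposal is accepted only if it keeps the graph simple.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
List cpp_double_edge_swap(IntegerMatrix adj, int target_swaps,
                          int max_attempts) {
  const int n = adj.ncol();
  std::vector<char> A(static_cast<size_t>(n) * n);
  std::vector<int> ea, eb;
  for (int j = 1; j < n; ++j) {
    for (int i = 0; i < j; ++i) {
      if (adj(i, j) != 0) {
        ea.push_back(i);
        eb.push_back(j);
        A[i + static_cast<size_t>(n) * j] = 1;
        A[j + static_cast<size_t>(n) * i] = 1;
      }
    }
  }
  const int m = static_cast<int>(ea.size());
  int accepted = 0, attempts = 0;
  if (m >= 2) {
    while (accepted < target_swaps && attempts < max_attempts) {
      ++attempts;
      int e1 = static_cast<int>(unif_rand() * m);
      int e2 = static_cast<int>(unif_rand() * m);
      if (e1 >= m) e1 = m - 1;
      if (e2 >= m) e2 = m - 1;
      bool coin = unif_rand() < 0.5;
      if (e1 == e2) continue;
      int a = ea[e1], b = eb[e1], c = ea[e2], d = eb[e2];
      if (a == c || a == d || b == c || b == d) continue;
      int x1, y1, x2, y2;
      if (coin) { x1 = a; y1 = d; x2 = c; y2 = b; }
      else      { x1 = a; y1 = c; x2 = b; y2 = d; }
      if (A[x1 + static_cast<size_t>(n) * y1] ||
          A[x2 + static_cast<size_t>(n) * y2]) continue;
      A[a + static_cast<size_t>(n) * b] = A[b + static_cast<size_t>(n) * a] = 0;
      A[c + static_cast<size_t>(n) * d] = A[d + static_cast<size_t>(n) * c] = 0;
      A[x1 + static_cast<size_t>(n) * y1] = A[y1 + static_cast<size_t>(n) * x1] = 1;
      A[x2 + static_cast<size_t>(n) * y2] = A[y2 + static_cast<size_t>(n) * x2] = 1;
      ea[e1] = std::min(x1, y1); eb[e1] = std::max(x1, y1);
      ea[e2] = std::min(x2, y2); eb[e2] = std::max(x2, y2);
      ++accepted;
    }
  }
  IntegerMatrix out(n, n);
  for (int k = 0; k < m; ++k) {
    out(ea[k], eb[k]) = 1;
    out(eb[k], ea[k]) = 1;
  }
  out.attr("dimnames") = adj.attr("dimnames");
  return List::create(_["adjacency"] = out,
                      _["accepted"] = accepted,
                      _["attempts"] = attempts);
}
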