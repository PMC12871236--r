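#include <Rcpp.h>
#include <vector>
#include <utility>
using namespace Rcpp;

// bases coded 1=A, 2=C, 3=G, 4=U; canonical pairs AU, GC, GU (both orders)
static inline bool canpair(int a, int b) {
  int x = a < b ? a : b, y = a < b ? b : a;
  return (x == 1 && y == 4) || (x == 2 && y == 3) || (x == 3 && y == 4);
}

// Maximum base-pair folding (Nussinov) over canonical pairs with a minimum
// hairpin-loop span: a pair (i, j) requires j - i - 1 >= min_loop.
// Traceback is deterministic: at each interval prefer "j unpaired", then the
// smallest admissible partner k for j.
// [[Rcpp::export]]
IntegerMatrix nussinov_pairs_cpp(IntegerVector seq, int min_loop) {
  int n = seq.size();
  if (n == 0) return IntegerMatrix(0, 2);
  IntegerMatrix M(n, n);
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = M(i, j - 1);  // j unpaired
      for (int k = i; k <= j - min_loop - 1; ++k) {
        if (!canpair(seq[k], seq[j])) continue;
        int v = 1;
        if (k > i) v += M(i, k - 1);
        if (k + 1 <= j - 1) v += M(k + 1, j - 1);
        if (v > best) best = v;
      }
      M(i, j) = best;
    }
  }
  std::vector<std::pair<int, int>> out;
  std::vector<std::pair<int, int>> stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (j - i < min_loop + 1) continue;
    if (M(i, j) == M(i, j - 1)) {           // prefer j unpaired
      stack.push_back(std::make_pair(i, j - 1));
      continue;
    }
    for (int k = i; k <= j - min_loop - 1; ++k) {  // then smallest k
      if (!canpair(seq[k], seq[j])) continue;
      int v = 1;
      if (k > i) v += M(i, k - 1);
      if (k + 1 <= j - 1) v += M(k + 1, j - 1);
      if (v == M(i, j)) {
        out.push_back(std::make_pair(k, j));
        if (k > i) stack.push_back(std::make_pair(i, k - 1));
        if (k + 1 <= j - 1) stack.push_back(std::make_pair(k + 1, j - 1));
        break;
      }
    }
  }
  IntegerMatrix res(out.size(), 2);
  for (size_t r = 0; r < out.size(); ++r) {
    res(r, 0) = out[r].first;
    res(r, 1) = out[r].second;
  }
  return res;
}
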