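#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Minimum-cost square assignment via the shortest-augmenting-path
// (Jonker-Volgenant style) formulation of the Hungarian method, O(n^3).
// Returns, for each row i (0-based), the column assigned to it.
// [[Rcpp::export]]
IntegerVector hungarian_cpp(NumericMatrix cost) {
  int n = cost.nrow();
  if (cost.ncol() != n) stop("cost matrix must be square");
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(n + 1, R_PosInf);
    std::vector<char> used(n + 1, 0);
    do {
      used[j0] = 1;
      int i0 = p[j0], j1 = 0;
      double delta = R_PosInf;
      for (int j = 1; j <= n; ++j) {
        if (used[j]) continue;
        double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0 != 0);
  }
  IntegerVector rowcol(n);
  for (int j = 1; j <= n; ++j) rowcol[p[j] - 1] = j - 1;
  return rowcol;
}
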