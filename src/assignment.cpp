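#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Exact linear assignment (minimum-cost perfect matching on a square cost
// matrix) via the Hungarian algorithm in its shortest-augmenting-path form
// with dual potentials, O(n^3). Returns, for each row, its assigned column.
// [[Rcpp::export]]
List cpp_assignment(NumericMatrix cost) {
  const int n = cost.nrow();
  if (cost.ncol() != n) stop("cost matrix must be square");
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0), minv(n + 1);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::fill(minv.begin(), minv.end(), INF);
    std::vector<bool> used(n + 1, false);
    do {
      used[j0] = true;
      int i0 = p[j0], j1 = 0;
      double delta = INF;
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
    do { int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }
  IntegerVector assign(n);
  double total = 0.0;
  for (int j = 1; j <= n; ++j) {
    assign[p[j] - 1] = j;
    total += cost(p[j] - 1, j - 1);
  }
  return List::create(_["assignment"] = assign, _["cost"] = total);
}
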