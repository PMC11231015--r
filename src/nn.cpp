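#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Nearest neighbour in Q for every point of P (brute force, exact).
// [[Rcpp::export]]
List cpp_nn(NumericMatrix P, NumericMatrix Q) {
  const int n = P.nrow(), m = Q.nrow();
  IntegerVector idx(n);
  NumericVector d2(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf; int bj = 0;
    const double x = P(i,0), y = P(i,1), z = P(i,2);
    for (int j = 0; j < m; ++j) {
      double dx = x - Q(j,0), dy = y - Q(j,1), dz = z - Q(j,2);
      double d = dx*dx + dy*dy + dz*dz;
      if (d < best) { best = d; bj = j; }
    }
    idx[i] = bj + 1; d2[i] = best;
  }
  return List::create(_["idx"] = idx, _["d2"] = d2);
}

// k nearest neighbours of each point within X (self included, first column).
// [[Rcpp::export]]
IntegerMatrix cpp_knn(NumericMatrix X, int k) {
  const int n = X.nrow();
  if (k > n) stop("k exceeds point count");
  IntegerMatrix out(n, k);
  std::vector< std::pair<double,int> > d(n);
  for (int i = 0; i < n; ++i) {
    const double x = X(i,0), y = X(i,1), z = X(i,2);
    for (int j = 0; j < n; ++j) {
      double dx = x - X(j,0), dy = y - X(j,1), dz = z - X(j,2);
      d[j] = std::make_pair(dx*dx + dy*dy + dz*dz, j);
    }
    std::partial_sort(d.begin(), d.begin() + k, d.end());
    for (int j = 0; j < k; ++j) out(i, j) = d[j].second + 1;
  }
  return out;
}

// Farthest point sampling: deterministic given the start index (1-based).
// [[Rcpp::export]]
IntegerVector cpp_fps(NumericMatrix X, int k, int start) {
  const int n = X.nrow();
  if (k > n) stop("k exceeds point count");
  IntegerVector out(k);
  std::vector<double> mind(n, R_PosInf);
  int cur = start - 1;
  for (int s = 0; s < k; ++s) {
    out[s] = cur + 1;
    const double x = X(cur,0), y = X(cur,1), z = X(cur,2);
    double best = -1.0; int bi = cur;
    for (int j = 0; j < n; ++j) {
      double dx = x - X(j,0), dy = y - X(j,1), dz = z - X(j,2);
      double d = dx*dx + dy*dy + dz*dz;
      if (d < mind[j]) mind[j] = d;
      if (mind[j] > best) { best = mind[j]; bi = j; }
    }
    cur = bi;
  }
  return out;
}
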