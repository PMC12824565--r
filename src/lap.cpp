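#include <Rcpp.h>
using namespace Rcpp;

//' Hungarian algorithm (shortest augmenting path with potentials) on a dense
//' square cost matrix. Returns the 1-based column assigned to each row.
//' Costs must be finite; use a large sentinel for forbidden pairings.
//' @noRd
// [[Rcpp::export]]
IntegerVector lap_cpp(NumericMatrix cost) {
  const int n = cost.nrow();
  if (cost.ncol() != n) stop("cost matrix must be square");
  const double INF = std::numeric_limits<double>::infinity();
  // 1-based internal arrays, classic O(n^3) formulation.
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(n + 1, INF);
    std::vector<char> used(n + 1, 0);
    do {
      used[j0] = 1;
      const int i0 = p[j0];
      double delta = INF;
      int j1 = 0;
      for (int j = 1; j <= n; ++j) {
        if (used[j]) continue;
        const double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) {
          minv[j] = cur;
          way[j] = j0;
        }
        if (minv[j] < delta) {
          delta = minv[j];
          j1 = j;
        }
      }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) {
          u[p[j]] += delta;
          v[j] -= delta;
        } else {
          minv[j] -= delta;
        }
      }
      j0 = j1;
    } while (p[j0] != 0);
    do {
      const int j1 = way[j0];
      p[j0] = p[j1];
      j0 = j1;
    } while (j0);
  }
  IntegerVector ans(n);
  for (int j = 1; j <= n; ++j)
    if (p[j] > 0) ans[p[j] - 1] = j;
  return ans;
}
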