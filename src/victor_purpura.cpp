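#include <Rcpp.h>
using namespace Rcpp;

// Exact Victor-Purpura distance between two sorted spike-time vectors.
// Edit operations: insert/delete a spike at cost 1, shift a spike by dt at
// cost q * |dt|. Standard O(n*m) dynamic program over spike indices:
//   G[i][j] = min(G[i-1][j] + 1, G[i][j-1] + 1,
//                 G[i-1][j-1] + q * |t1[i] - t2[j]|)
// Rolling rows keep memory at O(m).

// [[Rcpp::export(name = ".vp_distance_cpp")]]
double vp_distance_cpp(NumericVector t1, NumericVector t2, double q) {
  if (q < 0) stop("q must be non-negative");
  const int n = t1.size(), m = t2.size();
  if (n == 0) return m;
  if (m == 0) return n;
  std::vector<double> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    const double ti = t1[i - 1];
    for (int j = 1; j <= m; ++j) {
      double shift = prev[j - 1] + q * std::fabs(ti - t2[j - 1]);
      double del = prev[j] + 1.0;
      double ins = cur[j - 1] + 1.0;
      cur[j] = std::min(shift, std::min(del, ins));
    }
    std::swap(prev, cur);
  }
  return prev[m];
}
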