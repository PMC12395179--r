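#include <Rcpp.h>
using namespace Rcpp;

// Classic unconstrained DTW alignment cost with absolute-difference local
// cost and steps (i-1,j), (i,j-1), (i-1,j-1).
// [[Rcpp::export]]
double dtw_cost_cpp(NumericVector x, NumericVector y) {
  int n = x.size(), m = y.size();
  std::vector<double> prev(m + 1, R_PosInf), cur(m + 1, R_PosInf);
  prev[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = R_PosInf;
    for (int j = 1; j <= m; ++j) {
      double c = std::abs(x[i - 1] - y[j - 1]);
      double best = std::min(prev[j], std::min(cur[j - 1], prev[j - 1]));
      cur[j] = c + best;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}
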