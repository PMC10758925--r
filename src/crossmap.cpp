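#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Exhaustive K-nearest-neighbour cross-map prediction on a shadow manifold.
//
// pts:    m x E matrix of delay vectors, rows ordered by increasing time.
// target: length-m values of the target series aligned to the same rows.
// causal: restrict admissible neighbours of row q to rows j < q (earlier
//         time); otherwise all rows j != q are admissible.
// min_neighbors: in causal mode a row is predicted only when at least this
//         many past neighbours exist (burn-in rule); non-causal rows need
//         just one admissible neighbour.
//
// Ties in distance are broken by the smaller row (= earlier time) index.
// Weights: u_i = exp(-d_i / d_1), w_i = u_i / sum(u); if d_1 == 0 the
// weight is split uniformly over all zero-distance neighbours.
// [[Rcpp::export]]
List cross_map_core(const NumericMatrix& pts, const NumericVector& target,
                    int K, bool causal, int min_neighbors) {
  const int m = pts.nrow(), E = pts.ncol();
  NumericVector pred(m, NA_REAL);
  LogicalVector valid(m);
  IntegerVector n_used(m);
  std::vector<double> bd(K);
  std::vector<int> bi(K);

  for (int q = 0; q < m; ++q) {
    const int lim = causal ? q : m;
    int cnt = 0;
    for (int j = 0; j < lim; ++j) {
      if (j == q) continue;
      double d2 = 0.0;
      for (int c = 0; c < E; ++c) {
        const double diff = pts(q, c) - pts(j, c);
        d2 += diff * diff;
      }
      if (cnt < K) {
        int pos = cnt++;
        while (pos > 0 && d2 < bd[pos - 1]) {
          bd[pos] = bd[pos - 1]; bi[pos] = bi[pos - 1]; --pos;
        }
        bd[pos] = d2; bi[pos] = j;
      } else if (d2 < bd[K - 1]) {
        int pos = K - 1;
        while (pos > 0 && d2 < bd[pos - 1]) {
          bd[pos] = bd[pos - 1]; bi[pos] = bi[pos - 1]; --pos;
        }
        bd[pos] = d2; bi[pos] = j;
      }
    }
    n_used[q] = cnt;
    const bool ok = causal ? (cnt >= min_neighbors) : (cnt >= 1);
    valid[q] = ok;
    if (!ok) continue;

    if (bd[0] == 0.0) {
      int nz = 0;
      double p = 0.0;
      for (int k = 0; k < cnt; ++k) {
        if (bd[k] == 0.0) { p += target[bi[k]]; ++nz; }
      }
      pred[q] = p / nz;
    } else {
      const double d1 = std::sqrt(bd[0]);
      double s = 0.0, p = 0.0;
      for (int k = 0; k < cnt; ++k) {
        const double w = std::exp(-std::sqrt(bd[k]) / d1);
        s += w; p += w * target[bi[k]];
      }
      pred[q] = p / s;
    }
  }
  return List::create(_["pred"] = pred, _["valid"] = valid,
                      _["n_used"] = n_used);
}
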