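#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Count, for every row of `x`, the number of OTHER rows within Euclidean
// distance `r` (plus itself is added on the R side). Rows are sorted by
// the first coordinate so that only candidate pairs inside a window of
// width r on that coordinate are examined; worst case O(n^2) but near
// O(n k) on real feature clouds, where k is the typical neighborhood
// occupancy. Columns are cells' transformed features (d is small).
// [[Rcpp::export(name = ".radius_count")]]
IntegerVector radius_count(NumericMatrix x, double r) {
  const int n = x.nrow(), d = x.ncol();
  const double r2 = r * r;
  IntegerVector out(n);
  if (!R_FINITE(r)) {
    std::fill(out.begin(), out.end(), n - 1);
    return out;
  }

  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    return x(a, 0) < x(b, 0);
  });

  int lo = 0;
  for (int ii = 0; ii < n; ++ii) {
    const int i = ord[ii];
    const double xi0 = x(i, 0);
    while (xi0 - x(ord[lo], 0) > r) ++lo;
    for (int jj = lo; jj < ii; ++jj) {
      const int j = ord[jj];
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        const double diff = x(i, k) - x(j, k);
        s += diff * diff;
        if (s > r2) break;
      }
      if (s <= r2) { ++out[i]; ++out[j]; }
    }
  }
  return out;
}

// Nearest-neighbour (excluding self and exact duplicates, which sit at
// distance 0) Euclidean distance from each row of `query` to the rows of
// `x`. Used on a seeded subsample to set the density kernel radius; when
// every point is identical the result is infinite and the caller treats
// all densities as n.
// [[Rcpp::export(name = ".nn_dist")]]
NumericVector nn_dist(NumericMatrix query, NumericMatrix x) {
  const int nq = query.nrow(), n = x.nrow(), d = x.ncol();
  NumericVector out(nq);
  for (int i = 0; i < nq; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < n; ++j) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        const double diff = query(i, k) - x(j, k);
        s += diff * diff;
        if (s >= best) break;
      }
      if (s > 0.0 && s < best) best = s;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
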