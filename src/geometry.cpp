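#include <Rcpp.h>
using namespace Rcpp;

// Minimum Euclidean distance from each row of `a` (n x 3) to the point set
// `b` (m x 3).  Plain O(n*m) scan; point sets here are solvent lattices and
// protein atom lists (a few thousand points), for which this is fast enough
// and exactly equal to the brute-force definition.
// [[Rcpp::export(name = ".cp_min_dist")]]
NumericVector cp_min_dist(NumericMatrix a, NumericMatrix b) {
  const int n = a.nrow(), m = b.nrow();
  NumericVector out(n);
  if (m == 0) {
    std::fill(out.begin(), out.end(), R_PosInf);
    return out;
  }
  for (int i = 0; i < n; ++i) {
    const double ax = a(i, 0), ay = a(i, 1), az = a(i, 2);
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      const double dx = ax - b(j, 0), dy = ay - b(j, 1), dz = az - b(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Number of other points within radius r of each point (self excluded).
// [[Rcpp::export(name = ".cp_neighbor_counts")]]
IntegerVector cp_neighbor_counts(NumericMatrix x, double r) {
  const int n = x.nrow();
  const double r2 = r * r;
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    const double xi = x(i, 0), yi = x(i, 1), zi = x(i, 2);
    for (int j = i + 1; j < n; ++j) {
      const double dx = xi - x(j, 0), dy = yi - x(j, 1), dz = zi - x(j, 2);
      if (dx * dx + dy * dy + dz * dz <= r2) {
        out[i] += 1;
        out[j] += 1;
      }
    }
  }
  return out;
}

// Count of rows of `a` whose nearest distance to any row of `b` is <= r.
// Used by the residue contact rule: how many side-chain atoms of one residue
// lie within d_cut of any atom of the other.
// [[Rcpp::export(name = ".cp_count_within")]]
int cp_count_within(NumericMatrix a, NumericMatrix b, double r) {
  const int n = a.nrow(), m = b.nrow();
  const double r2 = r * r;
  int count = 0;
  for (int i = 0; i < n; ++i) {
    const double ax = a(i, 0), ay = a(i, 1), az = a(i, 2);
    for (int j = 0; j < m; ++j) {
      const double dx = ax - b(j, 0), dy = ay - b(j, 1), dz = az - b(j, 2);
      if (dx * dx + dy * dy + dz * dz <= r2) { ++count; break; }
    }
  }
  return count;
}
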