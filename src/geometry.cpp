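#include <Rcpp.h>
#include "geom.h"
using namespace Rcpp;

// Exact intersection test between two solid finite cylinders.
// centers/axes are length-3; axes must be unit vectors.
// [[Rcpp::export]]
bool cyl_overlap_cpp(NumericVector center_a, NumericVector axis_a,
                     NumericVector center_b, NumericVector axis_b,
                     double radius, double height) {
  Cyl A = {v3(center_a[0], center_a[1], center_a[2]),
           v3(axis_a[0], axis_a[1], axis_a[2]), radius, height / 2.0};
  Cyl B = {v3(center_b[0], center_b[1], center_b[2]),
           v3(axis_b[0], axis_b[1], axis_b[2]), radius, height / 2.0};
  return cyl_overlap(A, B);
}

// Vectorized overlap test: each row of `a` and `b` is (center, axis).
// [[Rcpp::export]]
LogicalVector cyl_overlap_many_cpp(NumericMatrix a, NumericMatrix b,
                                   double radius, double height) {
  int n = a.nrow();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    Cyl A = {v3(a(i, 0), a(i, 1), a(i, 2)),
             v3(a(i, 3), a(i, 4), a(i, 5)), radius, height / 2.0};
    Cyl B = {v3(b(i, 0), b(i, 1), b(i, 2)),
             v3(b(i, 3), b(i, 4), b(i, 5)), radius, height / 2.0};
    out[i] = cyl_overlap(A, B);
  }
  return out;
}

// Pair energy (u0 units) for each dimer row of an 18-column state matrix.
// Returns a matrix with columns (energy, feasible, stacked); infeasible rows
// get energy = +Inf.
// [[Rcpp::export]]
NumericMatrix dimer_energy_cpp(NumericMatrix state, double radius,
                               double height, double r0, double r1) {
  int n = state.nrow();
  NumericMatrix out(n, 3);
  std::vector<double> row(18);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < 18; ++j) row[j] = state(i, j);
    DimerE e = dimer_energy_row(row.data(), radius, height, r0, r1);
    out(i, 0) = e.feasible ? e.energy : R_PosInf;
    out(i, 1) = e.feasible ? 1.0 : 0.0;
    out(i, 2) = e.stacked ? 1.0 : 0.0;
  }
  return out;
}
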