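#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Histogram of intra-dimer pair distances for point-decorated dimers.
// pts: (n_dimers * pts_per_dimer) x 3, grouped by dimer (consecutive rows).
// Returns counts of the C(m,2) distances per dimer, pooled over dimers, in
// bins [k*bw, (k+1)*bw).  Distances beyond n_bins*bw are counted in the
// last bin (callers size the histogram from a geometric bound).
// [[Rcpp::export]]
NumericVector pair_hist_cpp(NumericMatrix pts, int n_dimers,
                            int pts_per_dimer, double bin_width, int n_bins) {
  NumericVector counts(n_bins);
  for (int d = 0; d < n_dimers; ++d) {
    int base = d * pts_per_dimer;
    for (int i = 0; i < pts_per_dimer; ++i) {
      double xi = pts(base + i, 0), yi = pts(base + i, 1), zi = pts(base + i, 2);
      for (int j = i + 1; j < pts_per_dimer; ++j) {
        double dx = xi - pts(base + j, 0);
        double dy = yi - pts(base + j, 1);
        double dz = zi - pts(base + j, 2);
        double r = std::sqrt(dx * dx + dy * dy + dz * dz);
        int b = (int)(r / bin_width);
        if (b >= n_bins) b = n_bins - 1;
        counts[b] += 1.0;
      }
    }
  }
  return counts;
}

// Direct Debye double sum, averaged over dimers:
//   I(q) = mean_d [ m + 2 * sum_{i<j in d} sinc(q r_ij) ]
// Kept as the exact reference path; the histogram transform is the fast one.
// [[Rcpp::export]]
NumericVector debye_direct_cpp(NumericMatrix pts, int n_dimers,
                               int pts_per_dimer, NumericVector q) {
  int nq = q.size();
  NumericVector I(nq);
  for (int d = 0; d < n_dimers; ++d) {
    int base = d * pts_per_dimer;
    for (int i = 0; i < pts_per_dimer; ++i) {
      for (int j = i + 1; j < pts_per_dimer; ++j) {
        double dx = pts(base + i, 0) - pts(base + j, 0);
        double dy = pts(base + i, 1) - pts(base + j, 1);
        double dz = pts(base + i, 2) - pts(base + j, 2);
        double r = std::sqrt(dx * dx + dy * dy + dz * dz);
        for (int k = 0; k < nq; ++k) {
          double x = q[k] * r;
          I[k] += 2.0 * (x < 1e-8 ? 1.0 : std::sin(x) / x);
        }
      }
    }
  }
  for (int k = 0; k < nq; ++k) I[k] = I[k] / n_dimers + pts_per_dimer;
  return I;
}
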