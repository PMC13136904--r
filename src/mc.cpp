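#include <Rcpp.h>
#include "geom.h"
using namespace Rcpp;

// Rodrigues rotation of v about unit axis k by angle th.
static inline V3 rotate_about(V3 v, V3 k, double th) {
  double c = std::cos(th), s = std::sin(th);
  return c * v + s * cross(k, v) + (dot(k, v) * (1.0 - c)) * k;
}

static inline V3 rand_unit_axis() {
  // isotropic direction from three normals
  V3 a = v3(R::norm_rand(), R::norm_rand(), R::norm_rand());
  double n = norm(a);
  if (n < 1e-12) return v3(0, 0, 1);
  return (1.0 / n) * a;
}

static inline void renormalize_frame(double *r, int off) {
  V3 u = v3(r[off + 3], r[off + 4], r[off + 5]);
  V3 w = v3(r[off + 6], r[off + 7], r[off + 8]);
  double nu = norm(u);
  u = (1.0 / nu) * u;
  w = w - dot(w, u) * u;
  double nw = norm(w);
  w = (1.0 / nw) * w;
  r[off + 3] = u.x; r[off + 4] = u.y; r[off + 5] = u.z;
  r[off + 6] = w.x; r[off + 7] = w.y; r[off + 8] = w.z;
}

// Canonical NVT* Metropolis run over independent two-cylinder dimers.
//
// state: n x 18 matrix (see geom.h for the row layout), already feasible.
// tstar: effective temperature k_B T / u0; +Inf accepts all feasible moves,
//        0 rejects any energy increase.
// One sweep = 2*n attempted single-cylinder moves (random translation or
// rotation of a random cylinder of a random dimer).  Move amplitudes are
// optionally tuned toward 30-50% acceptance during the first half of
// thermalization, then frozen so that production obeys detailed balance.
// [[Rcpp::export]]
List mc_run_cpp(NumericMatrix state_, double radius, double height,
                double r0, double r1, double tstar,
                int n_therm, int n_snapshots, int snap_interval,
                double max_trans, double max_rot, bool tune) {
  NumericMatrix state = clone(state_);
  int n = state.nrow();
  bool hot = !R_FINITE(tstar);  // T* = infinity code path
  int n_prod = n_snapshots * snap_interval;
  int n_sweeps = n_therm + n_prod;

  std::vector<double> energy(n);
  double etot = 0.0;
  std::vector<double> row(18);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < 18; ++j) row[j] = state(i, j);
    DimerE e = dimer_energy_row(row.data(), radius, height, r0, r1);
    if (!e.feasible) stop("initial state violates hard constraints (dimer %d)", i + 1);
    energy[i] = e.energy;
    etot += e.energy;
  }

  NumericVector energy_trace(n_sweeps);
  List snapshots(n_snapshots);
  NumericVector snapshot_energy(n_snapshots);
  double amp_t = max_trans, amp_r = max_rot;
  long acc_t = 0, att_t = 0, acc_r = 0, att_r = 0;       // production
  long win_acc_t = 0, win_att_t = 0, win_acc_r = 0, win_att_r = 0;  // tuning
  int snap_idx = 0;

  for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    bool in_therm = sweep < n_therm;
    bool tuning = tune && in_therm && sweep < n_therm / 2;
    for (int m = 0; m < 2 * n; ++m) {
      int i = (int)(R::unif_rand() * n);
      if (i >= n) i = n - 1;
      int off = (R::unif_rand() < 0.5) ? 0 : 9;
      bool is_trans = R::unif_rand() < 0.5;

      for (int j = 0; j < 18; ++j) row[j] = state(i, j);
      if (is_trans) {
        for (int k = 0; k < 3; ++k)
          row[off + k] += amp_t * (2.0 * R::unif_rand() - 1.0);
      } else {
        V3 k = rand_unit_axis();
        double th = amp_r * (2.0 * R::unif_rand() - 1.0);
        V3 u = v3(row[off + 3], row[off + 4], row[off + 5]);
        V3 w = v3(row[off + 6], row[off + 7], row[off + 8]);
        u = rotate_about(u, k, th);
        w = rotate_about(w, k, th);
        row[off + 3] = u.x; row[off + 4] = u.y; row[off + 5] = u.z;
        row[off + 6] = w.x; row[off + 7] = w.y; row[off + 8] = w.z;
        renormalize_frame(row.data(), off);
      }

      DimerE e = dimer_energy_row(row.data(), radius, height, r0, r1);
      bool accept = false;
      if (e.feasible) {
        double dE = e.energy - energy[i];
        if (hot) {
          accept = true;
        } else if (dE <= 0.0) {
          accept = true;
        } else if (tstar > 0.0) {
          accept = R::unif_rand() < std::exp(-dE / tstar);
        }
      }
      if (accept) {
        for (int j = 0; j < 18; ++j) state(i, j) = row[j];
        etot += e.energy - energy[i];
        energy[i] = e.energy;
      }
      if (tuning) {
        if (is_trans) { win_att_t++; win_acc_t += accept; }
        else          { win_att_r++; win_acc_r += accept; }
      } else if (!in_therm) {
        if (is_trans) { att_t++; acc_t += accept; }
        else          { att_r++; acc_r += accept; }
      }
    }
    if (tuning && ((sweep + 1) % 25 == 0)) {
      if (win_att_t > 0) {
        double f = (double)win_acc_t / win_att_t;
        if (f < 0.30) amp_t *= 0.8; else if (f > 0.50) amp_t *= 1.2;
        if (amp_t > 5.0) amp_t = 5.0;
        if (amp_t < 1e-3) amp_t = 1e-3;
      }
      if (win_att_r > 0) {
        double f = (double)win_acc_r / win_att_r;
        if (f < 0.30) amp_r *= 0.8; else if (f > 0.50) amp_r *= 1.2;
        if (amp_r > M_PI) amp_r = M_PI;
        if (amp_r < 1e-3) amp_r = 1e-3;
      }
      win_att_t = win_acc_t = win_att_r = win_acc_r = 0;
    }
    energy_trace[sweep] = etot;
    if (!in_therm && ((sweep - n_therm + 1) % snap_interval == 0)) {
      snapshots[snap_idx] = clone(state);
      snapshot_energy[snap_idx] = etot;
      snap_idx++;
    }
  }

  return List::create(
      _["snapshots"] = snapshots,
      _["snapshot_energy"] = snapshot_energy,
      _["energy_trace"] = energy_trace,
      _["final_state"] = state,
      _["acceptance"] = NumericVector::create(
          _["translation"] = att_t > 0 ? (double)acc_t / att_t : NA_REAL,
          _["rotation"] = att_r > 0 ? (double)acc_r / att_r : NA_REAL),
      _["amplitudes"] = NumericVector::create(
          _["translation"] = amp_t, _["rotation"] = amp_r));
}
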