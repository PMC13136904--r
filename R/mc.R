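#' Monte Carlo simulation settings
#'
#' Configuration for a canonical NVT* run over an ensemble of independent
#' dimers.  Since dimers do not interact with each other (only intra-dimer
#' energetics and hard constraints apply, appropriate for the dilute
#' solutions the model targets), the periodic box is a bookkeeping device:
#' its default size keeps the cylinder volume fraction at or below 0.5%.
#'
#' A sweep consists of `2 * n_dimers` attempted single-cylinder moves
#' (random translations or rotations).  Move amplitudes are tuned towards a
#' 30-50% acceptance rate during the first half of thermalization and then
#' frozen, so production sampling obeys detailed balance.
#'
#' @param n_dimers Number of dimers (the experimental-scale value is 3000;
#'   the default 300 is the desk-scale profile).
#' @param tstar Effective temperature T* = kB*T/u0; `0` (ground state,
#'   always stacked), a positive number, or `Inf` (no stacking bias).
#' @param box_length Cubic box edge in nm, or `NULL` to derive it from
#'   `volume_fraction` and the geometry at initialization.
#' @param volume_fraction Target cylinder volume fraction for the default box.
#' @param n_thermalization Thermalization sweeps before any snapshot.
#' @param n_snapshots Number of production snapshots (experimental-scale 50).
#' @param snapshot_interval Sweeps between snapshots (approximate
#'   decorrelation interval).
#' @param max_translation,max_rotation Initial move amplitudes (nm, rad).
#' @param seed Integer RNG seed; identical configurations reproduce
#'   bit-identical trajectories.
#' @param tune Tune move amplitudes during early thermalization.
#' @return An object of class `"simulation_config"`.
#' @export
simulation_config <- function(n_dimers = 300, tstar = Inf, box_length = NULL,
                              volume_fraction = 0.005,
                              n_thermalization = 400, n_snapshots = 10,
                              snapshot_interval = 20, max_translation = 0.5,
                              max_rotation = 0.6, seed = 1L, tune = TRUE) {
  stopifnot(n_dimers >= 1, n_thermalization >= 0, n_snapshots >= 1,
            snapshot_interval >= 1, max_translation > 0, max_rotation > 0)
  if (!(identical(tstar, Inf) || (is_number(tstar) && tstar >= 0)))
    stop("tstar must be a non-negative number or Inf")
  structure(list(n_dimers = as.integer(n_dimers), tstar = tstar,
                 box_length = box_length, volume_fraction = volume_fraction,
                 n_thermalization = as.integer(n_thermalization),
                 n_snapshots = as.integer(n_snapshots),
                 snapshot_interval = as.integer(snapshot_interval),
                 max_translation = max_translation, max_rotation = max_rotation,
                 seed = as.integer(seed), tune = isTRUE(tune)),
            class = "simulation_config")
}

resolve_box_length <- function(config, geometry) {
  if (!is.null(config$box_length)) return(config$box_length)
  v_cyl <- pi * geometry$radius^2 * geometry$height
  (config$n_dimers * 2 * v_cyl / config$volume_fraction)^(1 / 3)
}

#' Initialize an ensemble of stacked dimers
#'
#' Places `n_dimers` dimers in the box, each in the stacked conformation
#' (coaxial cylinders, facing bases almost in contact, linker patches
#' aligned), with uniformly random centers and uniformly random rigid-body
#' orientations.  By construction every dimer satisfies the hard constraints
#' and is stacked.
#'
#' @param config A [simulation_config()].
#' @param geometry A [cylinder_geometry()].
#' @param patches A [patch_spec()].
#' @return An `n_dimers x 18` state matrix of class `"g4_ensemble"` with the
#'   geometry and patches attached as attributes.
#' @export
initialize_ensemble <- function(config, geometry = cylinder_geometry(),
                                patches = patch_spec()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_dimers
  box <- resolve_box_length(config, geometry)
  h <- geometry$height / 2
  gap <- 1e-3  # facing bases separated by 1 pm: stacked, never overlapping
  rot <- random_rotation_images(n)
  u <- rot$ez
  w <- rot$ex
  centers <- matrix(runif(3 * n, 0, box), n, 3)
  ca <- centers - (h + gap / 2) * u
  cb <- centers + (h + gap / 2) * u
  state <- cbind(ca, u, w, cb, u, w)
  colnames(state) <- c(paste0(c("cx", "cy", "cz", "ux", "uy", "uz", "wx", "wy", "wz"), "_a"),
                       paste0(c("cx", "cy", "cz", "ux", "uy", "uz", "wx", "wy", "wz"), "_b"))
  en <- dimer_energy_cpp(state, geometry$radius, geometry$height,
                         patches$linker_radius, patches$stacking_radius)
  if (any(en[, 2] == 0)) stop("initialization produced an infeasible dimer")
  structure(state, geometry = geometry, patches = patches, box_length = box,
            class = c("g4_ensemble", "matrix", "array"))
}

#' Run a canonical NVT* Monte Carlo simulation
#'
#' Thermalizes the ensemble, then collects `n_snapshots` snapshots separated
#' by `snapshot_interval` sweeps.  The total stacking energy (in u0 units;
#' always equal to minus the number of stacked dimers) is recorded every
#' sweep.  A trend test on the production energy trace flags runs whose
#' energy still drifts; the flag is stored in the returned object and a
#' warning is emitted.
#'
#' @param config A [simulation_config()].
#' @param geometry A [cylinder_geometry()].
#' @param patches A [patch_spec()].
#' @param initial_state Optional starting ensemble (e.g. the `final_state`
#'   of a previous trajectory, useful for equilibration/ergodicity checks);
#'   defaults to a fresh all-stacked [initialize_ensemble()].
#' @return An object of class `"g4_trajectory"`: list with `snapshots` (list
#'   of state matrices), `snapshot_energy`, `energy_trace`, `acceptance`,
#'   `amplitudes`, `final_state`, `equilibrated`, plus the inputs.
#' @examples
#' \donttest{
#' traj <- run_mc(simulation_config(n_dimers = 50, tstar = 0,
#'                                  n_thermalization = 20, n_snapshots = 3))
#' stacked_fraction(traj)$p_st  # 1 at T* = 0 from a stacked start
#' }
#' @export
run_mc <- function(config, geometry = cylinder_geometry(), patches = patch_spec(),
                   initial_state = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(initial_state)) {
    state <- initialize_ensemble(config, geometry, patches)
  } else {
    state <- initial_state
    set.seed(config$seed)
  }
  res <- mc_run_cpp(unclass(state), geometry$radius, geometry$height,
                    patches$linker_radius, patches$stacking_radius,
                    config$tstar, config$n_thermalization, config$n_snapshots,
                    config$snapshot_interval, config$max_translation,
                    config$max_rotation, config$tune)
  prod_e <- res$energy_trace[-seq_len(config$n_thermalization)]
  equilibrated <- energy_trace_flat(prod_e)
  if (!equilibrated)
    warning("energy trace shows a trend over the production window; ",
            "increase n_thermalization")
  structure(list(snapshots = res$snapshots,
                 snapshot_energy = as.numeric(res$snapshot_energy),
                 energy_trace = as.numeric(res$energy_trace),
                 acceptance = res$acceptance, amplitudes = res$amplitudes,
                 final_state = res$final_state,
                 equilibrated = equilibrated, config = config,
                 geometry = geometry, patches = patches),
            class = "g4_trajectory")
}

# TRUE when the energy trace has no meaningful linear drift: the fitted
# change over the window must be small compared to the trace fluctuations.
energy_trace_flat <- function(e) {
  n <- length(e)
  if (n < 10 || sd(e) == 0) return(TRUE)
  t <- seq_len(n)
  fit <- lm(e ~ t)
  drift <- abs(coef(fit)[2]) * n
  drift <= 4 * sd(e)
}

# stacking indicator for every dimer row of a state matrix (vectorized)
ensemble_stacked <- function(state, geometry, patches) {
  h <- geometry$height / 2
  sa <- state[, 1:3, drop = FALSE] + h * state[, 4:6, drop = FALSE]
  sb <- state[, 10:12, drop = FALSE] - h * state[, 13:15, drop = FALSE]
  d2 <- rowSums((sa - sb)^2)
  d2 <= (2 * patches$stacking_radius)^2
}

#' Stacked fraction of a trajectory
#'
#' The central observable of the model: the mean fraction of dimers whose
#' facing stacking patch centers lie within the stacking well, averaged over
#' snapshots, with a between-snapshot standard error.
#'
#' @param trajectory A `"g4_trajectory"` from [run_mc()].
#' @return List with `p_st`, `std_error`, and `per_snapshot`.
#' @export
stacked_fraction <- function(trajectory) {
  stopifnot(inherits(trajectory, "g4_trajectory"))
  per <- vapply(trajectory$snapshots, function(s) {
    mean(ensemble_stacked(s, trajectory$geometry, trajectory$patches))
  }, numeric(1))
  se <- if (length(per) > 1) sd(per) / sqrt(length(per)) else 0
  list(p_st = mean(per), std_error = se, per_snapshot = per)
}

#' Geometric stacking probability at T* = infinity
#'
#' Independent rejection-sampling estimate of the probability that a dimer
#' drawn uniformly from the linker-constrained, overlap-free configuration
#' space is stacked.  This is the equilibrium stacked fraction when the
#' stacking well is switched off (T* = infinity) and serves as the reference
#' value for Monte Carlo validation.
#'
#' Cylinder A is held fixed; B's orientation is drawn uniformly from SO(3)
#' and its center uniformly from the ball (of constant volume) that the
#' linker well allows, which makes the proposal density uniform over the
#' linker-feasible set.  Overlapping proposals are rejected.
#'
#' @param geometry A [cylinder_geometry()].
#' @param patches A [patch_spec()].
#' @param n_samples Number of proposals.
#' @param seed Optional RNG seed.
#' @return List with `p_st`, `std_error`, `n_feasible`.
#' @export
pst_geometric_oracle <- function(geometry = cylinder_geometry(),
                                 patches = patch_spec(),
                                 n_samples = 2e5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  h <- geometry$height / 2
  R <- geometry$radius
  link_a <- c(R, 0, h)           # A at origin, axis z-hat, rim direction x-hat
  stack_a <- c(0, 0, h)
  rot <- random_rotation_images(n_samples)
  ub <- rot$ez
  wb <- rot$ex
  # uniform point in the ball of radius 2*R0 for the linker patch of B
  r0 <- 2 * patches$linker_radius
  dir <- matrix(rnorm(3 * n_samples), n_samples, 3)
  dir <- dir / sqrt(rowSums(dir^2))
  rad <- r0 * runif(n_samples)^(1 / 3)
  link_b <- sweep(rad * dir, 2, link_a, "+")
  cb <- link_b + h * ub - R * wb  # center from linker position and frame
  a_rows <- cbind(matrix(0, n_samples, 3),
                  matrix(c(0, 0, 1), n_samples, 3, byrow = TRUE))
  b_rows <- cbind(cb, ub)
  overlap <- cyl_overlap_many_cpp(a_rows, b_rows, R, geometry$height)
  feasible <- !overlap
  stack_b <- cb - h * ub
  d2 <- rowSums(sweep(stack_b, 2, stack_a)^2)
  stacked <- feasible & d2 <= (2 * patches$stacking_radius)^2
  n_f <- sum(feasible)
  if (n_f == 0) stop("no feasible samples; increase n_samples")
  p <- sum(stacked) / n_f
  list(p_st = p, std_error = sqrt(p * (1 - p) / n_f), n_feasible = n_f)
}
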