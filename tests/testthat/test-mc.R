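test_that("initialization places stacked, feasible, reproducible ensembles", {
  cfg <- simulation_config(n_dimers = 50, tstar = 0, seed = 7)
  geom <- cylinder_geometry()
  patches <- patch_spec()
  st <- initialize_ensemble(cfg, geom, patches)
  expect_equal(nrow(st), 50)
  expect_true(all(g4dimer:::ensemble_stacked(st, geom, patches)))
  en <- g4dimer:::dimer_energy_cpp(unclass(st), geom$radius, geom$height,
                                   patches$linker_radius, patches$stacking_radius)
  expect_true(all(en[, 2] == 1))
  expect_true(all(en[, 1] == -1))
  # same seed reproduces bit-identical ensembles
  st2 <- initialize_ensemble(cfg, geom, patches)
  expect_identical(unclass(st), unclass(st2))
  # density stays dilute in the default box
  v_cyl <- pi * geom$radius^2 * geom$height
  box <- attr(st, "box_length")
  expect_lt(50 * 2 * v_cyl / box^3, 0.01)
})

test_that("T* = 0 trajectories stay fully stacked and conserve the energy identity", {
  cfg <- simulation_config(n_dimers = 100, tstar = 0, n_thermalization = 100,
                           n_snapshots = 5, seed = 3)
  traj <- run_mc(cfg)
  sf <- stacked_fraction(traj)
  expect_identical(sf$p_st, 1)
  expect_identical(sf$std_error, 0)
  # total energy = -(number of stacked dimers) at every snapshot
  for (i in seq_along(traj$snapshots)) {
    n_stacked <- sum(g4dimer:::ensemble_stacked(traj$snapshots[[i]],
                                                traj$geometry, traj$patches))
    expect_equal(traj$snapshot_energy[i], -n_stacked)
  }
})

test_that("snapshots never violate hard constraints", {
  for (ts in c(0.5, Inf)) {
    cfg <- simulation_config(n_dimers = 80, tstar = ts, n_thermalization = 150,
                             n_snapshots = 5, seed = 13)
    traj <- suppressWarnings(run_mc(cfg))
    for (s in traj$snapshots) {
      en <- g4dimer:::dimer_energy_cpp(s, traj$geometry$radius,
                                       traj$geometry$height,
                                       traj$patches$linker_radius,
                                       traj$patches$stacking_radius)
      expect_true(all(en[, 2] == 1))
    }
  }
})

test_that("trajectories are bit-reproducible from the seed", {
  cfg <- simulation_config(n_dimers = 40, tstar = 1, n_thermalization = 60,
                           n_snapshots = 3, seed = 42)
  t1 <- suppressWarnings(run_mc(cfg))
  t2 <- suppressWarnings(run_mc(cfg))
  expect_identical(t1$snapshots, t2$snapshots)
  expect_identical(t1$energy_trace, t2$energy_trace)
})

test_that("T* = infinity sampling matches the geometric rejection oracle", {
  oracle <- pst_geometric_oracle(n_samples = 4e5, seed = 5)
  cfg <- simulation_config(n_dimers = 400, tstar = Inf, n_thermalization = 300,
                           n_snapshots = 60, snapshot_interval = 15, seed = 8)
  sf <- stacked_fraction(suppressWarnings(run_mc(cfg)))
  z <- (sf$p_st - oracle$p_st) /
    sqrt(sf$std_error^2 + oracle$std_error^2)
  expect_lt(abs(z), 3)
})

test_that("finite-T* occupancy matches the Boltzmann-weighted geometric odds", {
  # detailed-balance check: the stacked/unstacked odds at T* must equal the
  # geometric odds (T* = infinity) amplified by exp(u0 / kB T) = exp(1/T*)
  oracle <- pst_geometric_oracle(n_samples = 6e5, seed = 15)
  odds_geo <- oracle$p_st / (1 - oracle$p_st)
  tstar <- 0.5
  cfg <- simulation_config(n_dimers = 400, tstar = tstar,
                           n_thermalization = 400, n_snapshots = 60,
                           snapshot_interval = 15, seed = 21)
  sf <- stacked_fraction(suppressWarnings(run_mc(cfg)))
  p_pred <- odds_geo * exp(1 / tstar) / (1 + odds_geo * exp(1 / tstar))
  se_pred <- p_pred * (1 - p_pred) *
    (oracle$std_error / (oracle$p_st * (1 - oracle$p_st)))
  z <- (sf$p_st - p_pred) / sqrt(sf$std_error^2 + se_pred^2)
  expect_lt(abs(z), 3)
})

test_that("stacked and unstacked starts converge to the same equilibrium", {
  tstar <- 0.4
  cfg_a <- simulation_config(n_dimers = 300, tstar = tstar,
                             n_thermalization = 500, n_snapshots = 40,
                             snapshot_interval = 15, seed = 31)
  sf_a <- stacked_fraction(suppressWarnings(run_mc(cfg_a)))
  # unstack first with a hot run, then equilibrate at the target T*
  hot <- simulation_config(n_dimers = 300, tstar = Inf, n_thermalization = 200,
                           n_snapshots = 1, seed = 32)
  hot_traj <- suppressWarnings(run_mc(hot))
  cfg_b <- simulation_config(n_dimers = 300, tstar = tstar,
                             n_thermalization = 500, n_snapshots = 40,
                             snapshot_interval = 15, seed = 33)
  sf_b <- stacked_fraction(suppressWarnings(
    run_mc(cfg_b, initial_state = hot_traj$final_state)))
  z <- (sf_a$p_st - sf_b$p_st) / sqrt(sf_a$std_error^2 + sf_b$std_error^2)
  expect_lt(abs(z), 3)
})

test_that("stacked_fraction averages snapshots with a between-snapshot error", {
  cfg <- simulation_config(n_dimers = 10, tstar = 0, n_thermalization = 10,
                           n_snapshots = 4, seed = 2)
  traj <- run_mc(cfg)
  # hand-build a trajectory with alternating half-stacked snapshots
  half <- traj$snapshots[[1]]
  H <- traj$geometry$height
  unstacked_row <- c(c(0, 0, 0), c(0, 0, 1), c(1, 0, 0),
                     c(0, 0, H + 0.8), c(0, 0, 1), c(1, 0, 0))
  half[1:5, ] <- matrix(unstacked_row, 5, 18, byrow = TRUE)
  fake <- traj
  fake$snapshots <- list(traj$snapshots[[1]], half)
  sf <- stacked_fraction(fake)
  expect_equal(sf$p_st, 0.75)
  expect_equal(sf$per_snapshot, c(1, 0.5))
})
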