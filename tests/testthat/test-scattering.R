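test_that("point decoration is uniform in the cylinder volume", {
  geom <- cylinder_geometry()
  pts <- single_cylinder_points(1, geom, points_per_cylinder = 1e5, seed = 9)
  p <- pts$points
  # sample mean near the center (3 sigma of the standard error)
  se_xy <- sd(p[, 1]) / sqrt(nrow(p))
  expect_lt(abs(mean(p[, 1])), 3 * se_xy)
  expect_lt(abs(mean(p[, 3])), 3 * sd(p[, 3]) / sqrt(nrow(p)))
  # empirical Rg^2 matches R^2/2 + H^2/12 within 0.5%
  rg2 <- mean(rowSums(sweep(p, 2, colMeans(p))^2))
  rg2_th <- geom$radius^2 / 2 + geom$height^2 / 12
  expect_lt(abs(rg2 / rg2_th - 1), 0.005)
  # seed determinism
  pts2 <- single_cylinder_points(1, geom, points_per_cylinder = 1e5, seed = 9)
  expect_identical(pts$points, pts2$points)
})

test_that("decorated dimer points land inside their cylinders", {
  set.seed(4)
  geom <- cylinder_geometry()
  cfg <- simulation_config(n_dimers = 5, tstar = 0, seed = 6)
  st <- initialize_ensemble(cfg, geom, patch_spec())
  dec <- decorate_points(unclass(st), geom, points_per_cylinder = 200)
  m <- 200
  for (d in 1:5) {
    rows_a <- ((d - 1) * 2 * m + 1):((d - 1) * 2 * m + m)
    rows_b <- rows_a + m
    expect_true(all(oracle_in_cyl(dec$points[rows_a, ], st[d, 1:3], st[d, 4:6],
                                  geom$radius, geom$height + 1e-9)))
    expect_true(all(oracle_in_cyl(dec$points[rows_b, ], st[d, 10:12], st[d, 13:15],
                                  geom$radius, geom$height + 1e-9)))
  }
})

test_that("Debye intensity reproduces trivial and closed-form cases", {
  q <- default_q_grid(50)
  # one point per dimer: I(Q) = 1 for all Q
  one <- list(points = matrix(rnorm(30), 10, 3), n_dimers = 10L,
              pts_per_dimer = 1L)
  expect_equal(debye_intensity(one, q, method = "direct")$intensity,
               rep(1, 50))
  # two points at fixed separation: I proportional to 2(1 + sinc(QR))
  set.seed(8)
  R <- 2.3; n2 <- 5000
  dirs <- matrix(rnorm(3 * n2), n2, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  pts <- matrix(0, 2 * n2, 3)
  pts[seq(2, 2 * n2, 2), ] <- R * dirs
  two <- list(points = pts, n_dimers = n2, pts_per_dimer = 2L)
  # I = (m + 2*sinc)/m^2 with m = 2, so 4*I = 2 + 2*sinc(QR) = S(Q)
  got <- debye_intensity(two, q, method = "direct")$intensity
  expect_equal(4 * got, closed_form_s(q, R), tolerance = 1e-12)
})

test_that("histogram and direct Debye sums agree within 0.2%", {
  geom <- cylinder_geometry()
  sh <- shared_saxs()
  set.seed(12)
  cfg <- simulation_config(n_dimers = 60, tstar = Inf, n_thermalization = 100,
                           n_snapshots = 1, seed = 14)
  traj <- suppressWarnings(run_mc(cfg))
  dec <- decorate_points(traj$snapshots[[1]], geom, points_per_cylinder = 60)
  q <- default_q_grid(60)
  ih <- debye_intensity(dec, q, method = "histogram", bin_width = 0.02)
  id <- debye_intensity(dec, q, method = "direct")
  expect_lt(max(abs(ih$intensity / id$intensity - 1)), 0.002)
})

test_that("Debye intensity is invariant under rigid motion of each dimer", {
  set.seed(21)
  n <- 20; m <- 30
  pts <- matrix(rnorm(n * m * 3), n * m, 3)
  obj <- list(points = pts, n_dimers = n, pts_per_dimer = m)
  q <- default_q_grid(40)
  i0 <- debye_intensity(obj, q, method = "direct")$intensity
  moved <- pts
  for (d in seq_len(n)) {
    rows <- ((d - 1) * m + 1):(d * m)
    Q <- rand_rotation()
    moved[rows, ] <- t(Q %*% t(pts[rows, ])) +
      matrix(rnorm(3, 0, 50), m, 3, byrow = TRUE)
  }
  i1 <- debye_intensity(list(points = moved, n_dimers = n, pts_per_dimer = m),
                        q, method = "direct")$intensity
  expect_equal(i1, i0, tolerance = 1e-10)
})

test_that("cylinder form factor has the right normalization and Guinier slope", {
  geom <- cylinder_geometry()
  q <- c(1e-6, seq(0.02, 0.3, by = 0.02))
  P <- cylinder_form_factor(q, geom)$intensity
  expect_equal(P[1], 1, tolerance = 1e-8)
  # ln P ~ -q^2 Rg^2 / 3 at small q
  fit <- lm(log(P[-1]) ~ I(q[-1]^2))
  rg2 <- -3 * coef(fit)[[2]]
  expect_equal(rg2, geom$radius^2 / 2 + geom$height^2 / 12, tolerance = 0.01)
})

test_that("point-cloud Debye matches the quadrature form factor", {
  cyl <- shared_cylinder_debye()
  sel <- cyl$q <= 3
  expect_lt(max(abs(cyl$I[sel] / cyl$P[sel] - 1)), 0.01)
})

test_that("closed-form dimer structure factor has the stated limits", {
  expect_equal(closed_form_s(1e-14, 3.59), 4)
  expect_equal(closed_form_s(pi / 3.59, 3.59), 2)
  expect_error(closed_form_s(1, -1), "positive")
  # matches an orientation-sampling oracle at random (Q, R)
  set.seed(33)
  for (i in 1:10) {
    qv <- runif(1, 0.2, 4); R <- runif(1, 1, 5)
    z <- runif(2e5, -1, 1)       # cos(theta) of random orientations
    est <- 2 * (1 + mean(cos(qv * R * z)))
    se <- 2 * sd(cos(qv * R * z)) / sqrt(length(z))
    expect_lt(abs(est - closed_form_s(qv, R)), 4 * se + 1e-12)
  }
})

test_that("Guinier fit recovers an exact model and brackets mixtures", {
  q <- default_q_grid()
  rg_true <- 2.10
  prof <- saxs_profile(q, exp(-q^2 * rg_true^2 / 3),
                       sigma = pmax(exp(-q^2 * rg_true^2 / 3) * 0.01, 1e-10))
  gf <- guinier_rg(prof)
  expect_equal(gf$rg, rg_true, tolerance = 0.01 / rg_true)
  expect_equal(gf$i0, 1, tolerance = 0.01)
  expect_lte(gf$q_rg_max, 1.3 + 1e-9)
  # a mixed ensemble lies between the all-stacked and all-unstacked values
  sh <- shared_saxs()
  rg0 <- guinier_rg(sh$i0)$rg
  rgI <- guinier_rg(sh$i_inf)$rg
  rgm <- guinier_rg(sh$i_exp)$rg
  expect_lt(rg0, rgI)   # stacked ensembles are more compact
  expect_gt(rgm, rg0)
  expect_lt(rgm, rgI)
  # no admissible window on a rising profile
  bad <- saxs_profile(q, 1 + q^2)
  expect_error(guinier_rg(bad), "Guinier range")
})

test_that("p(r) inversion reproduces the analytic sphere distribution", {
  a <- 2
  q <- default_q_grid()
  qa <- q * a
  I <- (3 * (sin(qa) - qa * cos(qa)) / qa^3)^2
  prof <- saxs_profile(q, I, sigma = pmax(I * 0.005, 1e-10))
  pf <- pofr(prof, d_max = 2 * a)
  expect_equal(pf$p[1], 0)
  expect_equal(pf$p[length(pf$p)], 0)
  x <- pf$r / a
  p_true <- 3 * x^2 * (1 - 0.75 * x + x^3 / 16) / a
  dr <- pf$r[2] - pf$r[1]
  p_est <- pf$p / (sum(pf$p) * dr)
  l2 <- sqrt(sum((p_est - p_true)^2) / sum(p_true^2))
  expect_lt(l2, 0.02)
  expect_equal(pf$rg_real, sqrt(3 / 5) * a, tolerance = 0.01)
})

test_that("reciprocal and real-space Rg agree on monomer-like profiles", {
  geom <- cylinder_geometry()
  q <- default_q_grid()
  P <- cylinder_form_factor(q, geom)$intensity
  set.seed(17)
  sig <- pmax(P * 0.005, 1e-8)
  prof <- saxs_profile(q, P + rnorm(length(q), 0, sig), sigma = sig)
  rg_rec <- guinier_rg(prof)$rg
  d_max <- sqrt(geom$height^2 + (2 * geom$radius)^2)
  rg_real <- pofr(prof, d_max = d_max)$rg_real
  expect_lt(abs(rg_rec - rg_real) / rg_real, 0.03)
})

test_that("p(r) of a simulated ensemble matches the decorated pair histogram", {
  sh <- shared_saxs()
  # model-free oracle: pair-distance histogram of decorated points of a
  # stacking-free ensemble vs the IFT of its own intensity
  set.seed(23)
  cfg <- simulation_config(n_dimers = 150, tstar = Inf, n_thermalization = 200,
                           n_snapshots = 4, seed = 51)
  traj <- suppressWarnings(run_mc(cfg))
  geom <- traj$geometry
  dec <- decorate_points(traj$snapshots[[1]], geom, points_per_cylinder = 60)
  acc <- g4dimer:::pair_hist_accumulate(dec, 0.1)
  r_mid <- (seq_along(acc$counts) - 0.5) * 0.1
  h_norm <- acc$counts / (sum(acc$counts) * 0.1)
  d_max <- r_mid[max(which(acc$counts > 0))] + 0.1
  pf <- pofr(sh$i_inf, d_max = d_max, n_r = 81)
  p_interp <- approx(pf$r, pf$p / (sum(pf$p) * (pf$r[2] - pf$r[1])),
                     r_mid, rule = 2)$y
  keep <- h_norm > 0.01 * max(h_norm)
  l2 <- sqrt(sum((p_interp[keep] - h_norm[keep])^2) / sum(h_norm[keep]^2))
  expect_lt(l2, 0.15)
})

test_that("Kratky transform is scale invariant and distinguishes architectures", {
  sh <- shared_saxs()
  g0 <- guinier_rg(sh$i0)
  k1 <- kratky(sh$i0, i0 = g0$i0)
  scaled <- saxs_profile(sh$i0$q, sh$i0$intensity * 7.3)
  k2 <- kratky(scaled, i0 = g0$i0 * 7.3)
  expect_equal(k2$kratky, k1$kratky, tolerance = 1e-12)
  # compact stacked ensemble: single bell; unstacked dimer: two features
  expect_equal(kratky_features(k1), 1)
  kI <- kratky(sh$i_inf, i0 = guinier_rg(sh$i_inf)$i0)
  expect_equal(kratky_features(kI), 2)
  expect_error(kratky(sh$i0, i0 = -1), "I\\(0\\)")
})
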