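#' Synthetic SAXS dataset at known stacked fraction
#'
#' Emulates an experimental dimer SAXS measurement: runs the hard-cylinder
#' model at T* = 0 (fully stacked) and T* = infinity (stacking-free), forms
#' the mixture I = p_st I0 + (1 - p_st) I_inf on the experimental Q range,
#' and applies Q-dependent Gaussian noise with relative standard deviation
#' sigma_rel(Q) = alpha + beta / sqrt(I(Q)/I(0)) - about 1% at low Q,
#' growing where the signal is weak, mimicking synchrotron bioSAXS data.
#'
#' @param p_st_true True stacked fraction in [0, 1].
#' @param geometry A [cylinder_geometry()].
#' @param patches A [patch_spec()].
#' @param q Q grid (nm^-1).
#' @param noise Length-2 vector `c(alpha, beta)` of the relative-noise model.
#' @param n_dimers,n_snapshots,points_per_cylinder Simulation sizes; the
#'   defaults are the desk-scale profile (the experimental-scale profile is
#'   3000 dimers, 50 snapshots, 100 points per cylinder via
#'   `experimental_scale = TRUE`).
#' @param seed Integer seed controlling both simulations and the noise.
#' @param experimental_scale Use the experimental-scale simulation sizes.
#' @return List with `i_exp`, `i0`, `i_inf` ([saxs_profile()]s) and `truth`
#'   (list of all generator parameters).
#' @export
gen_saxs <- function(p_st_true, geometry = cylinder_geometry(),
                     patches = patch_spec(), q = default_q_grid(),
                     noise = c(alpha = 0.005, beta = 0.005),
                     n_dimers = 300, n_snapshots = 10,
                     points_per_cylinder = 50, seed = 1L,
                     experimental_scale = FALSE) {
  if (!is_number(p_st_true) || p_st_true < 0 || p_st_true > 1)
    stop("p_st_true must be in [0, 1]")
  if (any(noise < 0)) stop("noise parameters must be non-negative")
  if (experimental_scale) {
    n_dimers <- 3000; n_snapshots <- 50; points_per_cylinder <- 100
  }
  seed <- as.integer(seed)
  cfg0 <- simulation_config(n_dimers = n_dimers, tstar = 0,
                            n_snapshots = n_snapshots, seed = seed)
  cfgI <- simulation_config(n_dimers = n_dimers, tstar = Inf,
                            n_snapshots = n_snapshots, seed = seed + 1L)
  t0 <- run_mc(cfg0, geometry, patches)
  tI <- run_mc(cfgI, geometry, patches)
  set.seed(seed + 2L)
  i0 <- simulate_intensity(t0, q, points_per_cylinder)
  i_inf <- simulate_intensity(tI, q, points_per_cylinder)
  mix <- p_st_true * i0$intensity + (1 - p_st_true) * i_inf$intensity
  rel <- noise[[1]] + noise[[2]] / sqrt(mix / mix[1])
  sigma <- abs(mix) * rel
  i_exp <- saxs_profile(q, mix + rnorm(length(q), 0, sigma), sigma = sigma)
  list(i_exp = i_exp, i0 = i0, i_inf = i_inf,
       truth = list(p_st = p_st_true, geometry = geometry, patches = patches,
                    noise = noise, n_dimers = n_dimers,
                    n_snapshots = n_snapshots,
                    points_per_cylinder = points_per_cylinder, seed = seed))
}

#' Synthetic intensity-ratio dataset at known distances
#'
#' Evaluates the closed-form ratio model
#' R(Q) = k (1 + sinc(Q R_cm_T)) / (1 + sinc(Q R_cm_T+L)) on a Q grid and
#' adds relative Gaussian noise.  Default distances are on the scale of the
#' telomeric dimer (free ~3.6 nm, compacted ~3.2 nm).
#'
#' @param r_cm_t Free-dimer center-of-mass distance (nm).
#' @param r_cm_tl Bound-dimer distance (nm).
#' @param k Scale prefactor.
#' @param noise Relative Gaussian noise level.
#' @param q Q grid; defaults to the low-Q portion of [default_q_grid()]
#'   where the ratio carries structure-factor information.
#' @param seed Integer seed.
#' @return A data.frame (`q`, `ratio`, `sigma`) with a `truth` attribute.
#' @export
gen_ratio <- function(r_cm_t = 3.59, r_cm_tl = 3.18, k = 1, noise = 0.01,
                      q = NULL, seed = 1L) {
  if (r_cm_t <= 0 || r_cm_tl <= 0) stop("distances must be positive")
  if (is.null(q)) {
    q <- default_q_grid()
    q <- q[q <= 2.5]
  }
  set.seed(as.integer(seed))
  r <- ratio_model(q, r_cm_t, r_cm_tl, k)
  sigma <- abs(r) * noise
  out <- data.frame(q = q, ratio = r + rnorm(length(q), 0, sigma), sigma = sigma)
  attr(out, "truth") <- list(r_cm_t = r_cm_t, r_cm_tl = r_cm_tl, k = k,
                             noise = noise, seed = as.integer(seed))
  out
}

# Gaussian-band basis spectra mimicking the CD signatures of the three
# species: folded hybrid G4 (max ~290 nm, shoulder ~270 nm, min ~240 nm),
# a parallel-like intermediate (max ~265 nm, min ~242 nm), and a weak
# largely featureless unfolded state.
default_cd_bands <- function() {
  list(
    folded = rbind(c(290, 9, 26), c(268, 9, 10), c(240, 8, -12)),
    intermediate = rbind(c(264, 9, 28), c(242, 7, -14), c(290, 10, 5)),
    unfolded = rbind(c(272, 20, 6), c(244, 11, -4))
  )
}

gaussian_bands <- function(wavelengths, bands) {
  rowSums(vapply(seq_len(nrow(bands)), function(i) {
    bands[i, 3] * exp(-0.5 * ((wavelengths - bands[i, 1]) / bands[i, 2])^2)
  }, numeric(length(wavelengths))))
}

#' Synthetic CD melting surface at known thermodynamics
#'
#' Builds D = B F(T) + noise, where the columns of B are Gaussian-band
#' basis spectra of the folded, intermediate, and unfolded species and F(T)
#' holds the three-state fractions of the sequential unfolding model.  The
#' default thermodynamics place the headline melting temperature (folded
#' fraction = 1/2) near 62 degrees C, the value typical of free telomeric
#' G4s in potassium buffer.
#'
#' @param wavelengths Wavelength grid (nm).
#' @param temperatures Temperature grid (degrees C).
#' @param dh1,tm1,dh2,tm2 Transition enthalpies (kJ/mol) and midpoints
#'   (degrees C) of the sequential model.
#' @param noise_sd Gaussian noise standard deviation (mdeg).
#' @param bands Basis-band specification as in `default_cd_bands()`:
#'   list of matrices with rows (center nm, width nm, amplitude mdeg).
#' @param seed Integer seed.
#' @return List with `matrix` (a [cd_melting_matrix()]) and `truth`
#'   (generator parameters, basis spectra, fraction curves).
#' @export
gen_cd_melt <- function(wavelengths = seq(220, 330, by = 2),
                        temperatures = seq(24, 100, by = 2),
                        dh1 = 200, tm1 = 62.5, dh2 = 250, tm2 = 70,
                        noise_sd = 0.15, bands = default_cd_bands(),
                        seed = 1L) {
  set.seed(as.integer(seed))
  B <- vapply(bands, function(b) gaussian_bands(wavelengths, b),
              numeric(length(wavelengths)))
  FR <- t(as.matrix(three_state_fractions(temperatures, dh1, tm1, dh2, tm2)[, -1]))
  D <- B %*% FR
  Dn <- D + matrix(rnorm(length(D), 0, noise_sd), nrow(D), ncol(D))
  list(matrix = cd_melting_matrix(wavelengths, temperatures, Dn),
       truth = list(dh1 = dh1, tm1 = tm1, dh2 = dh2, tm2 = tm2,
                    noise_sd = noise_sd, basis = B, fractions = t(FR),
                    noiseless = D, seed = as.integer(seed)))
}
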