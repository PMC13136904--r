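#' CD melting matrix
#'
#' Ellipticity as a function of wavelength (rows) and temperature (columns),
#' the D matrix of the SVD melting analysis.  Typical experiments cover
#' 220-330 nm and 24-100 degrees C in 2 degree steps.
#'
#' @param wavelengths Strictly increasing wavelength grid (nm).
#' @param temperatures Strictly increasing temperature grid (degrees C).
#' @param ellipticity Matrix (mdeg), `length(wavelengths)` x
#'   `length(temperatures)`; columns are the spectra at each temperature.
#' @return Object of class `"cd_melting_matrix"`.
#' @export
cd_melting_matrix <- function(wavelengths, temperatures, ellipticity) {
  wavelengths <- as.numeric(wavelengths)
  temperatures <- as.numeric(temperatures)
  ellipticity <- as.matrix(ellipticity)
  if (any(diff(wavelengths) <= 0)) stop("wavelengths must be strictly increasing")
  if (any(diff(temperatures) <= 0)) stop("temperatures must be strictly increasing")
  if (!all(dim(ellipticity) == c(length(wavelengths), length(temperatures))))
    stop("ellipticity dimensions do not match the grids")
  if (any(!is.finite(ellipticity))) stop("ellipticity must be finite")
  structure(list(wavelengths = wavelengths, temperatures = temperatures,
                 ellipticity = ellipticity), class = "cd_melting_matrix")
}

#' Single CD spectrum
#'
#' @param wavelengths Strictly increasing wavelength grid (nm).
#' @param ellipticity Ellipticity values (mdeg).
#' @return Object of class `"cd_spectrum"`.
#' @export
cd_spectrum <- function(wavelengths, ellipticity) {
  wavelengths <- as.numeric(wavelengths)
  ellipticity <- as.numeric(ellipticity)
  if (any(diff(wavelengths) <= 0)) stop("wavelengths must be strictly increasing")
  if (length(wavelengths) != length(ellipticity)) stop("length mismatch")
  structure(list(wavelengths = wavelengths, ellipticity = ellipticity),
            class = "cd_spectrum")
}

#' Singular value decomposition of a CD melting matrix
#'
#' Factorizes D = U S V^T.  U columns are basis spectra, S the singular
#' values (non-increasing), and V columns amplitude-vs-temperature profiles.
#' A consistent sign convention is applied: the largest-magnitude element of
#' each U column is made positive (V adjusted accordingly).  Per-component
#' relative variances S_j^2 / sum(S^2) and lag-1 autocorrelation
#' coefficients of the unit-normalized U and V columns are attached for the
#' significance analysis.
#'
#' @param d A [cd_melting_matrix()].
#' @return Object of class `"svd_result"`: `u`, `s`, `v`,
#'   `relative_variance`, `autocorrelation_u`, `autocorrelation_v`,
#'   `wavelengths`, `temperatures`.
#' @export
svd_decompose <- function(d) {
  stopifnot(inherits(d, "cd_melting_matrix"))
  if (length(d$temperatures) < 3 || length(d$wavelengths) < 3)
    stop("need at least 3 temperatures and 3 wavelengths")
  dec <- svd(d$ellipticity)
  for (j in seq_along(dec$d)) {
    i_max <- which.max(abs(dec$u[, j]))
    if (dec$u[i_max, j] < 0) {
      dec$u[, j] <- -dec$u[, j]
      dec$v[, j] <- -dec$v[, j]
    }
  }
  lag1 <- function(x) {
    x <- x / sqrt(sum(x^2))
    sum(x[-length(x)] * x[-1])
  }
  structure(list(u = dec$u, s = dec$d, v = dec$v,
                 relative_variance = dec$d^2 / sum(dec$d^2),
                 autocorrelation_u = apply(dec$u, 2, lag1),
                 autocorrelation_v = apply(dec$v, 2, lag1),
                 wavelengths = d$wavelengths, temperatures = d$temperatures),
            class = "svd_result")
}

#' Number of significant SVD components
#'
#' A component is significant when its relative variance exceeds
#' `variance_floor` and the lag-1 autocorrelation coefficients of both its
#' basis spectrum (U column) and its amplitude profile (V column) exceed
#' `ac_threshold` (smooth, signal-like vectors have autocorrelation near 1;
#' noise vectors near 0).  The count of significant leading components is
#' returned: counting stops at the first non-significant component.
#'
#' @param res An [svd_decompose()] result.
#' @param ac_threshold Autocorrelation significance threshold (default 0.8).
#' @param variance_floor Minimum relative variance (default 0.1%).
#' @return Integer count.
#' @export
significant_components <- function(res, ac_threshold = 0.8, variance_floor = 0.001) {
  stopifnot(inherits(res, "svd_result"))
  sig <- res$relative_variance > variance_floor &
    res$autocorrelation_u > ac_threshold &
    res$autocorrelation_v > ac_threshold
  n <- 0L
  for (s in sig) {
    if (!s) break
    n <- n + 1L
  }
  n
}

# van't Hoff equilibrium constants and three-state species fractions on a
# kelvin grid; theta = (dH1 [kJ/mol], Tm1 [K], dH2, Tm2)
three_state_fractions_k <- function(theta, t_kelvin) {
  R_gas <- 8.314462618e-3  # kJ/(mol K)
  k1 <- exp(-theta[1] / R_gas * (1 / t_kelvin - 1 / theta[2]))
  k2 <- exp(-theta[3] / R_gas * (1 / t_kelvin - 1 / theta[4]))
  f_f <- 1 / (1 + k1 + k1 * k2)
  cbind(f_f = f_f, f_i = k1 * f_f, f_u = k1 * k2 * f_f)
}

#' Species fractions of the sequential three-state unfolding model
#'
#' Folded <-> Intermediate <-> Unfolded with van't Hoff equilibrium
#' constants K_i(T) = exp(-dH_i/R (1/T - 1/Tm_i)).  Fractions sum to one at
#' every temperature.
#'
#' @param temperatures_c Temperatures in degrees C.
#' @param dh1,tm1 Enthalpy (kJ/mol) and midpoint (degrees C) of the first
#'   transition.
#' @param dh2,tm2 Same for the second transition.
#' @return data.frame with `temperature`, `f_folded`, `f_intermediate`,
#'   `f_unfolded`.
#' @export
three_state_fractions <- function(temperatures_c, dh1, tm1, dh2, tm2) {
  fr <- three_state_fractions_k(c(dh1, tm1 + 273.15, dh2, tm2 + 273.15),
                                temperatures_c + 273.15)
  data.frame(temperature = temperatures_c, f_folded = fr[, 1],
             f_intermediate = fr[, 2], f_unfolded = fr[, 3])
}

#' Global three-state fit of SVD amplitude vectors
#'
#' Globally fits the significant V columns (weighted by their singular
#' values) as linear combinations of the species fractions of a sequential
#' folded <-> intermediate <-> unfolded model with van't Hoff temperature
#' dependence.  The thermodynamic parameters are shared by all components;
#' the per-component amplitude coefficients are profiled out by linear least
#' squares at each step (variable projection).  Levenberg-Marquardt with
#' multiple starting midpoints; Tm2 is parametrized as Tm1 + dT (dT >= 0) so
#' the transitions are ordered by construction.
#'
#' The headline melting temperature is reported as the temperature where
#' the folded fraction crosses 1/2.
#'
#' @param res An [svd_decompose()] result.
#' @param n_components Number of leading V columns to fit; default
#'   [significant_components()].
#' @param ac_threshold,variance_floor Passed to [significant_components()]
#'   when `n_components` is NULL.
#' @param dh_bounds Allowed enthalpy range (kJ/mol).
#' @return Object of class `"three_state_fit"`: `dh1`, `tm1`, `dh2`, `tm2`
#'   (+ `_se`), `tm_headline`, `amplitudes` (3 x n_components),
#'   `fractions` (data.frame), `chi2_reduced`, `at_bound`, `n_components`.
#' @export
fit_three_state <- function(res, n_components = NULL, ac_threshold = 0.8,
                            variance_floor = 0.001, dh_bounds = c(30, 1500)) {
  stopifnot(inherits(res, "svd_result"))
  if (is.null(n_components))
    n_components <- significant_components(res, ac_threshold, variance_floor)
  if (n_components < 1) stop("no significant components to fit")
  n_components <- min(n_components, ncol(res$v))
  t_c <- res$temperatures
  t_k <- t_c + 273.15
  Y <- res$v[, seq_len(n_components), drop = FALSE] %*%
    diag(res$s[seq_len(n_components)], n_components)

  # theta = (dH1, Tm1[K], dH2, dT[K])
  resid_fn <- function(theta) {
    th <- c(theta[1], theta[2], theta[3], theta[2] + theta[4])
    FR <- three_state_fractions_k(th, t_k)
    as.vector(vapply(seq_len(n_components), function(j) {
      cf <- qr.solve(FR, Y[, j])
      Y[, j] - FR %*% cf
    }, numeric(length(t_k))))
  }
  lower <- c(dh_bounds[1], min(t_k) - 20, dh_bounds[1], 0)
  upper <- c(dh_bounds[2], max(t_k) + 40, dh_bounds[2], 80)
  t_span <- range(t_k)
  starts <- expand.grid(
    tm1 = quantile(t_k, c(0.3, 0.45, 0.6)),
    dt = c(5, 12, 25))
  best <- NULL; best_ssr <- Inf
  for (i in seq_len(nrow(starts))) {
    p0 <- c(200, starts$tm1[i], 250, starts$dt[i])
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_fn, lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(fit$fvec^2)
    if (ssr < best_ssr) { best <- fit; best_ssr <- ssr }
  }
  if (is.null(best)) stop("three-state fit failed to converge from any start")
  p <- best$par
  theta <- c(p[1], p[2], p[3], p[2] + p[4])
  FR <- three_state_fractions_k(theta, t_k)
  amps <- vapply(seq_len(n_components), function(j) qr.solve(FR, Y[, j]),
                 numeric(3))
  rownames(amps) <- c("folded", "intermediate", "unfolded")
  dof <- max(length(t_k) * n_components - (4 + 3 * n_components), 1)
  chi2_red <- best_ssr / dof
  cov <- tryCatch(chi2_red * solve(best$hessian),
                  error = function(e) matrix(NA_real_, 4, 4))
  se <- sqrt(pmax(diag(cov), 0))
  # se of Tm2 = se(Tm1 + dT) by linear propagation
  tm2_se <- if (all(is.finite(cov[c(2, 4), c(2, 4)]))) {
    sqrt(cov[2, 2] + cov[4, 4] + 2 * cov[2, 4])
  } else NA_real_
  at_bound <- any(abs(p - lower) < 1e-6) || any(abs(p - upper) < 1e-6)
  fr_df <- data.frame(temperature = t_c, f_folded = FR[, 1],
                      f_intermediate = FR[, 2], f_unfolded = FR[, 3])
  tm_headline <- headline_tm(theta, range(t_k))
  structure(list(dh1 = theta[1], dh1_se = se[1],
                 tm1 = theta[2] - 273.15, tm1_se = se[2],
                 dh2 = theta[3], dh2_se = se[3],
                 tm2 = theta[4] - 273.15, tm2_se = tm2_se,
                 tm_headline = tm_headline,
                 amplitudes = amps, fractions = fr_df,
                 chi2_reduced = chi2_red, at_bound = at_bound,
                 n_components = n_components, converged = best$info %in% 1:4),
            class = "three_state_fit")
}

# temperature (deg C) where the folded fraction crosses 1/2
headline_tm <- function(theta, t_k_range) {
  f <- function(tk) three_state_fractions_k(theta, tk)[, 1] - 0.5
  lo <- t_k_range[1] - 30; hi <- t_k_range[2] + 60
  if (f(lo) < 0 || f(hi) > 0) return(NA_real_)
  uniroot(f, c(lo, hi), tol = 1e-6)$root - 273.15
}

#' @export
print.three_state_fit <- function(x, ...) {
  cat(sprintf(paste0("Three-state fit (%d components): dH1 = %.0f kJ/mol, ",
                     "Tm1 = %.1f C; dH2 = %.0f kJ/mol, Tm2 = %.1f C; ",
                     "headline Tm = %.1f C%s\n"),
              x$n_components, x$dh1, x$tm1, x$dh2, x$tm2, x$tm_headline,
              if (x$at_bound) " [parameter at bound]" else ""))
  invisible(x)
}

#' RSQ spectral dissimilarity
#'
#' Root of the sum of squared pointwise differences between two CD spectra
#' sampled on the same wavelength grid:
#' \deqn{RSQ = \sqrt{\sum_i [CD_a(\lambda_i) - CD_b(\lambda_i)]^2}}
#' in mdeg.  A global measure of how much two CD profiles - hence the
#' underlying G4 topologies - differ.
#'
#' @param spec_a,spec_b [cd_spectrum()] objects.
#' @param resample Permit linear resampling of `spec_b` onto `spec_a`'s grid
#'   when the grids differ (logged via a message); otherwise differing grids
#'   are an error.
#' @return RSQ value in mdeg.
#' @examples
#' a <- cd_spectrum(250:260, rep(1, 11))
#' b <- cd_spectrum(250:260, rep(0, 11))
#' rsq(a, b)  # sqrt(11)
#' @export
rsq <- function(spec_a, spec_b, resample = FALSE) {
  stopifnot(inherits(spec_a, "cd_spectrum"), inherits(spec_b, "cd_spectrum"))
  if (!isTRUE(all.equal(spec_a$wavelengths, spec_b$wavelengths))) {
    if (!resample) stop("wavelength grids differ; set resample = TRUE to interpolate")
    message("resampling spec_b onto spec_a's wavelength grid")
    yb <- approx(spec_b$wavelengths, spec_b$ellipticity, spec_a$wavelengths,
                 rule = 2)$y
  } else {
    yb <- spec_b$ellipticity
  }
  sqrt(sum((spec_a$ellipticity - yb)^2))
}
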