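#' SAXS intensity profile
#'
#' Container for a small-angle scattering curve: a strictly increasing
#' positive Q grid with intensities and optional per-point uncertainties.
#' Q is stored internally in nm^-1; profiles supplied in Angstrom^-1 are
#' converted (x 10) at construction.
#'
#' @param q Wave-vector transfer grid.
#' @param intensity Intensities (arbitrary units), finite.
#' @param sigma Optional uncertainties, positive where present.
#' @param q_unit `"nm^-1"` (default) or `"A^-1"`.
#' @return An object of class `"saxs_profile"`.
#' @export
saxs_profile <- function(q, intensity, sigma = NULL, q_unit = c("nm^-1", "A^-1")) {
  q_unit <- match.arg(q_unit)
  q <- as.numeric(q)
  intensity <- as.numeric(intensity)
  if (q_unit == "A^-1") q <- q * 10
  if (length(q) != length(intensity)) stop("q and intensity lengths differ")
  if (any(!is.finite(q)) || any(q <= 0)) stop("q must be finite and positive")
  if (any(diff(q) <= 0)) stop("q must be strictly increasing")
  if (any(!is.finite(intensity))) stop("intensity must be finite")
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(q)) stop("sigma length differs from q")
    if (any(!is.finite(sigma)) || any(sigma <= 0)) stop("sigma must be positive")
  }
  structure(list(q = q, intensity = intensity, sigma = sigma, q_unit = "nm^-1"),
            class = "saxs_profile")
}

#' @export
print.saxs_profile <- function(x, ...) {
  cat(sprintf("SAXS profile: %d points, Q in [%.4g, %.4g] nm^-1%s\n",
              length(x$q), min(x$q), max(x$q),
              if (is.null(x$sigma)) "" else ", with uncertainties"))
  invisible(x)
}

#' Default synthetic Q grid
#'
#' 200 log-spaced points over 0.044-5.21 nm^-1, the measured wave-vector
#' transfer range of the BM29-class experiments this package emulates.
#'
#' @param n Number of points.
#' @return Numeric vector (nm^-1).
#' @export
default_q_grid <- function(n = 200) logspace(0.044, 5.21, n)

#' Decorate a configuration snapshot with scattering points
#'
#' Replaces every cylinder by `points_per_cylinder` points drawn uniformly
#' from its volume (uniform disk x uniform height, mapped through the pose),
#' the standard bead representation used to compute Debye-sum intensities.
#' Fresh points should be drawn for every snapshot.
#'
#' @param state A state matrix (one row per dimer, as in [run_mc()]
#'   snapshots or [initialize_ensemble()]).
#' @param geometry A [cylinder_geometry()].
#' @param points_per_cylinder Points per cylinder (experimental-scale 100).
#' @param seed Optional RNG seed for reproducible point sets.
#' @return List with `points` (matrix, rows grouped by dimer: all points of
#'   cylinder A then B), `n_dimers`, `pts_per_dimer`.
#' @export
decorate_points <- function(state, geometry, points_per_cylinder = 100,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(points_per_cylinder >= 1)
  n <- nrow(state)
  m <- as.integer(points_per_cylinder)
  # per-cylinder world frames: (e1, e2, u) with e1 = rim direction w
  centers <- rbind(state[, 1:3, drop = FALSE], state[, 10:12, drop = FALSE])
  u <- rbind(state[, 4:6, drop = FALSE], state[, 13:15, drop = FALSE])
  w <- rbind(state[, 7:9, drop = FALSE], state[, 16:18, drop = FALSE])
  e2 <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
              u[, 3] * w[, 1] - u[, 1] * w[, 3],
              u[, 1] * w[, 2] - u[, 2] * w[, 1])
  # interleave A/B so that rows are grouped per dimer
  ord <- as.vector(rbind(seq_len(n), seq_len(n) + n))
  centers <- centers[ord, , drop = FALSE]
  u <- u[ord, , drop = FALSE]; w <- w[ord, , drop = FALSE]
  e2 <- e2[ord, , drop = FALSE]
  ncyl <- 2L * n
  idx <- rep(seq_len(ncyl), each = m)
  npts <- ncyl * m
  th <- runif(npts, 0, 2 * pi)
  rad <- geometry$radius * sqrt(runif(npts))
  z <- runif(npts, -geometry$height / 2, geometry$height / 2)
  x <- rad * cos(th); y <- rad * sin(th)
  pts <- centers[idx, ] + x * w[idx, ] + y * e2[idx, ] + z * u[idx, ]
  list(points = pts, n_dimers = n, pts_per_dimer = 2L * m)
}

#' Debye-sum SAXS intensity of point-decorated dimers
#'
#' Computes the orientation-free Debye sum restricted to intra-dimer pairs
#' (dimers scatter independently in the dilute ensemble):
#' \deqn{I(Q) = \frac{1}{n_d m^2} \sum_d \sum_{i,j \in d}
#'       \frac{\sin(Q r_{ij})}{Q r_{ij}}}
#' normalized so that I(0) = 1.  The default path histograms the pair
#' distances (bin width `bin_width` nm) and transforms the histogram; the
#' direct O(m^2) double sum is retained as the exact reference and must
#' agree within 0.2% at the default bin width.
#'
#' @param points Output of [decorate_points()].
#' @param q Q grid (nm^-1).
#' @param method `"histogram"` (fast, default) or `"direct"`.
#' @param bin_width Histogram bin width in nm.
#' @param self_term Keep the i = j self terms (the physical intensity of the
#'   m-point representation, with its 1/m sampling floor at high Q).  With
#'   `FALSE` the i != j pair sum is normalized by m(m-1), an unbiased
#'   estimator of the continuum form/structure factor, appropriate when
#'   comparing against closed-form expressions.
#' @return A [saxs_profile()] with I(0) = 1 normalization.
#' @export
debye_intensity <- function(points, q, method = c("histogram", "direct"),
                            bin_width = 0.02, self_term = TRUE) {
  method <- match.arg(method)
  if (points$n_dimers < 1) stop("empty input")
  m <- points$pts_per_dimer
  if (method == "direct") {
    I <- debye_direct_cpp(points$points, points$n_dimers, m, q)
    I <- if (self_term) I / m^2 else (I - m) / (m^2 - m)
    return(saxs_profile(q, I))
  }
  acc <- pair_hist_accumulate(points, bin_width)
  I <- pair_hist_transform(acc$counts, acc$bin_width, m, points$n_dimers, q,
                           self_term)
  saxs_profile(q, I)
}

#' Point sets for isolated single cylinders
#'
#' Convenience generator for form-factor validation: `n_configs`
#' independent point clouds, each uniform in one cylinder, packaged like
#' [decorate_points()] output (each cloud is one independent scatterer).
#'
#' @param n_configs Number of independent single-cylinder configurations.
#' @param geometry A [cylinder_geometry()].
#' @param points_per_cylinder Points per configuration.
#' @param seed Optional RNG seed.
#' @return A points list as from [decorate_points()].
#' @export
single_cylinder_points <- function(n_configs, geometry, points_per_cylinder = 100,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- as.integer(points_per_cylinder)
  npts <- n_configs * m
  th <- runif(npts, 0, 2 * pi)
  rad <- geometry$radius * sqrt(runif(npts))
  z <- runif(npts, -geometry$height / 2, geometry$height / 2)
  list(points = cbind(rad * cos(th), rad * sin(th), z),
       n_dimers = as.integer(n_configs), pts_per_dimer = m)
}

# histogram of intra-dimer pair distances with a safe geometric bound
pair_hist_accumulate <- function(points, bin_width) {
  pts <- points$points
  m <- points$pts_per_dimer
  n <- points$n_dimers
  grp <- rep(seq_len(n), each = m)
  cen <- rowsum(pts, grp) / m
  r2 <- rowSums((pts - cen[grp, , drop = FALSE])^2)
  dmax <- 2 * sqrt(max(r2)) + bin_width
  n_bins <- as.integer(ceiling(dmax / bin_width)) + 1L
  counts <- pair_hist_cpp(pts, n, m, bin_width, n_bins)
  list(counts = counts, bin_width = bin_width)
}

pair_hist_transform <- function(counts, bin_width, pts_per_dimer,
                                n_dimer_configs, q, self_term = TRUE) {
  r_mid <- (seq_along(counts) - 0.5) * bin_width
  keep <- counts > 0
  S <- outer(q, r_mid[keep]) # q x r
  pair_sum <- 2 * as.vector(sinc(S) %*% counts[keep]) / n_dimer_configs
  if (self_term) {
    (pts_per_dimer + pair_sum) / pts_per_dimer^2
  } else {
    pair_sum / (pts_per_dimer^2 - pts_per_dimer)
  }
}

#' Simulated SAXS intensity of a trajectory
#'
#' Pools all snapshots of a Monte Carlo trajectory (each dimer configuration
#' counts as an independent scatterer), decorates every cylinder with fresh
#' uniform points, and evaluates the Debye intensity on `q`.
#'
#' @param trajectory A `"g4_trajectory"`.
#' @param q Q grid (nm^-1); default [default_q_grid()].
#' @param points_per_cylinder Scattering points per cylinder.
#' @param bin_width Pair-distance histogram bin width (nm).
#' @param seed Optional RNG seed for the decoration.
#' @return A [saxs_profile()] with I(0) = 1.
#' @export
simulate_intensity <- function(trajectory, q = default_q_grid(),
                               points_per_cylinder = 100, bin_width = 0.02,
                               seed = NULL) {
  stopifnot(inherits(trajectory, "g4_trajectory"))
  if (!is.null(seed)) set.seed(seed)
  counts <- NULL
  m <- 2L * as.integer(points_per_cylinder)
  n_tot <- 0L
  for (s in trajectory$snapshots) {
    pts <- decorate_points(s, trajectory$geometry, points_per_cylinder)
    acc <- pair_hist_accumulate(pts, bin_width)
    if (is.null(counts)) {
      counts <- acc$counts
    } else {
      if (length(acc$counts) > length(counts))
        counts <- c(counts, numeric(length(acc$counts) - length(counts)))
      counts[seq_along(acc$counts)] <- counts[seq_along(acc$counts)] + acc$counts
    }
    n_tot <- n_tot + pts$n_dimers
  }
  I <- pair_hist_transform(counts, bin_width, m, n_tot, q)
  saxs_profile(q, I)
}

#' Orientation-averaged form factor of a uniform cylinder
#'
#' \deqn{P(Q) = \int_0^{\pi/2} \left[\frac{2 J_1(QR\sin\alpha)}{QR\sin\alpha}
#'   \cdot \frac{\sin(Q \tfrac{H}{2}\cos\alpha)}{Q \tfrac{H}{2}\cos\alpha}
#'   \right]^2 \sin\alpha \, d\alpha}
#' evaluated by adaptive quadrature, with P(0) = 1.
#'
#' @param q Q grid (nm^-1).
#' @param geometry A [cylinder_geometry()].
#' @return A [saxs_profile()].
#' @export
cylinder_form_factor <- function(q, geometry) {
  stopifnot(inherits(geometry, "cylinder_geometry"))
  R <- geometry$radius; h <- geometry$height / 2
  j1norm <- function(x) ifelse(abs(x) < 1e-6, 1 - x^2 / 8, 2 * besselJ(x, 1) / x)
  P <- vapply(q, function(qi) {
    if (qi < 1e-10) return(1)
    f <- function(a) {
      amp <- j1norm(qi * R * sin(a)) * sinc(qi * h * cos(a))
      amp^2 * sin(a)
    }
    integrate(f, 0, pi / 2, rel.tol = 1e-8)$value
  }, numeric(1))
  saxs_profile(q, P)
}

#' Closed-form dimer structure factor
#'
#' The structure factor of two point-like units at fixed center-of-mass
#' separation R, orientation averaged:
#' \deqn{S(Q) = 2\left(1 + \frac{\sin(QR)}{QR}\right)}
#' with the analytic limit S(0) = 4.
#'
#' @param q Q values (nm^-1).
#' @param R Center-of-mass separation (nm, > 0).
#' @return Numeric vector of S(Q) values.
#' @export
closed_form_s <- function(q, R) {
  if (!is_number(R) || R <= 0) stop("R must be positive")
  2 * (1 + sinc(q * R))
}

#' Guinier fit with automatic range selection
#'
#' Estimates the radius of gyration Rg and forward intensity I(0) from the
#' low-Q behaviour ln I = ln I(0) - Q^2 Rg^2 / 3.  Candidate fitting windows
#' are scanned over the low-Q region; windows must satisfy
#' `q_max * Rg <= q_rg_limit` and contain at least `min_points` points, and
#' among admissible windows the longest (best quality among ties) is chosen,
#' emulating automated Guinier-range selection.
#'
#' @param profile A [saxs_profile()] with at least `min_points` low-Q points.
#' @param q_rg_limit Upper limit for q*Rg in the fitted window (globular
#'   convention 1.3).
#' @param min_points Minimum points in the window.
#' @param min_r_squared Quality threshold for a window to be admissible
#'   without penalty.
#' @return An object of class `"guinier_fit"`: `rg`, `rg_se`, `i0`, `i0_se`,
#'   `q_range`, `n_points`, `r_squared`, `residual_runs_z`.
#' @export
guinier_rg <- function(profile, q_rg_limit = 1.3, min_points = 10,
                       min_r_squared = 0.99) {
  stopifnot(inherits(profile, "saxs_profile"))
  ok <- profile$intensity > 0
  q <- profile$q[ok]; I <- profile$intensity[ok]
  sig <- if (is.null(profile$sigma)) NULL else profile$sigma[ok]
  n <- length(q)
  if (n < min_points) stop("Guinier range not found: too few positive points")
  x <- q^2
  y <- log(I)
  wt <- if (is.null(sig)) rep(1, n) else (I / sig)^2

  fit_window <- function(i1, i2) {
    xs <- x[i1:i2]; ys <- y[i1:i2]; ws <- wt[i1:i2]
    W <- sum(ws); mx <- sum(ws * xs) / W; my <- sum(ws * ys) / W
    sxx <- sum(ws * (xs - mx)^2)
    if (sxx <= 0) return(NULL)
    slope <- sum(ws * (xs - mx) * (ys - my)) / sxx
    inter <- my - slope * mx
    res <- ys - (inter + slope * xs)
    m <- i2 - i1 + 1
    s2 <- sum(ws * res^2) / max(m - 2, 1)
    tss <- sum(ws * (ys - my)^2)
    r2 <- if (tss > 0) 1 - sum(ws * res^2) / tss else 0
    list(slope = slope, inter = inter, r2 = r2,
         slope_se = sqrt(s2 / sxx),
         inter_se = sqrt(s2 * (1 / W + mx^2 / sxx)),
         res = res, i1 = i1, i2 = i2, n = m)
  }

  # rough Rg from the first window to bound the scan region
  rough <- fit_window(1, min(n, max(min_points, 15)))
  rg0 <- if (!is.null(rough) && rough$slope < 0) sqrt(-3 * rough$slope) else NA
  q_hi <- if (is.finite(rg0) && rg0 > 0) 1.5 * q_rg_limit / rg0 else max(q)
  i_hi <- max(which(q <= max(q_hi, q[min(min_points, n)])))

  best <- NULL
  starts <- unique(round(seq(1, max(1, i_hi - min_points + 1), length.out = 25)))
  for (i1 in starts) {
    ends <- unique(round(seq(i1 + min_points - 1, i_hi, length.out = 25)))
    ends <- ends[ends <= n]
    for (i2 in ends) {
      f <- fit_window(i1, i2)
      if (is.null(f) || f$slope >= 0) next
      rg <- sqrt(-3 * f$slope)
      if (q[i2] * rg > q_rg_limit) next
      score <- (f$n + 100 * (f$r2 >= min_r_squared)) * max(f$r2, 0)
      if (is.null(best) || score > best$score) {
        best <- f; best$score <- score; best$rg <- rg
      }
    }
  }
  if (is.null(best)) stop("Guinier range not found")
  rg <- best$rg
  rg_se <- 3 * best$slope_se / (2 * rg)
  i0 <- exp(best$inter)
  # residual randomness: z statistic of the runs test on residual signs
  s <- sign(best$res); s <- s[s != 0]
  runs_z <- NA_real_
  if (length(s) > 3) {
    runs <- 1 + sum(diff(s) != 0)
    n1 <- sum(s > 0); n2 <- sum(s < 0)
    if (n1 > 0 && n2 > 0) {
      mu <- 2 * n1 * n2 / (n1 + n2) + 1
      v <- 2 * n1 * n2 * (2 * n1 * n2 - n1 - n2) /
        ((n1 + n2)^2 * (n1 + n2 - 1))
      if (v > 0) runs_z <- (runs - mu) / sqrt(v)
    }
  }
  structure(list(rg = rg, rg_se = rg_se, i0 = i0, i0_se = i0 * best$inter_se,
                 q_range = c(q[best$i1], q[best$i2]), n_points = best$n,
                 r_squared = best$r2, residual_runs_z = runs_z,
                 q_rg_max = q[best$i2] * rg),
            class = "guinier_fit")
}

#' @export
print.guinier_fit <- function(x, ...) {
  cat(sprintf("Guinier fit: Rg = %.3f +/- %.3f nm, I(0) = %.4g (%d pts, q*Rg <= %.2f)\n",
              x$rg, x$rg_se, x$i0, x$n_points, x$q_rg_max))
  invisible(x)
}

#' Pair-distance distribution by regularized indirect Fourier transform
#'
#' Reconstructs p(r) on [0, D_max] from I(Q) by inverting
#' \deqn{I(Q) = \int_0^{D_{max}} p(r) \frac{\sin(Qr)}{Qr} dr}
#' with endpoint constraints p(0) = p(D_max) = 0 and a second-difference
#' smoothness penalty.  The regularization weight is chosen as the largest
#' weight whose misfit stays within 10% of the best attainable misfit (a
#' consistency/L-curve heuristic).  Also returns the real-space radius of
#' gyration, Rg^2 = \eqn{\int r^2 p \, dr / (2 \int p \, dr)}.
#'
#' @param profile A [saxs_profile()].
#' @param d_max Maximum particle dimension (nm).
#' @param n_r Number of r-grid points.
#' @param lambda Optional fixed regularization weight (skips the heuristic).
#' @return Object of class `"pofr"`: `r`, `p`, `d_max`, `rg_real`, `i0`,
#'   `lambda`, `chi2_reduced`.
#' @export
pofr <- function(profile, d_max, n_r = 101, lambda = NULL) {
  stopifnot(inherits(profile, "saxs_profile"))
  if (!is_number(d_max) || d_max <= 0) stop("d_max must be positive")
  q <- profile$q; I <- profile$intensity
  sig <- if (is.null(profile$sigma)) rep(max(abs(I)) * 1e-3, length(q)) else profile$sigma
  r <- seq(0, d_max, length.out = n_r)
  dr <- r[2] - r[1]
  interior <- 2:(n_r - 1)
  A <- sinc(outer(q, r[interior])) * dr    # nq x (n_r-2)
  Aw <- A / sig
  yw <- I / sig
  # second-difference operator over the full grid with fixed zero endpoints
  nf <- length(interior)
  L <- matrix(0, nf, nf)
  for (i in seq_len(nf)) {
    L[i, i] <- -2
    if (i > 1) L[i, i - 1] <- 1
    if (i < nf) L[i, i + 1] <- 1
  }
  AtA <- crossprod(Aw); Aty <- crossprod(Aw, yw); LtL <- crossprod(L)
  scale0 <- sum(diag(AtA)) / sum(diag(LtL))
  solve_l <- function(lam) {
    p <- tryCatch(solve(AtA + lam * scale0 * LtL, Aty),
                  error = function(e) NULL)
    if (is.null(p)) return(NULL)
    chi2 <- sum((Aw %*% p - yw)^2) / max(length(q) - nf, length(q) * 0.5)
    list(p = as.numeric(p), chi2 = chi2)
  }
  if (!is.null(lambda)) {
    sol <- solve_l(lambda)
    if (is.null(sol)) stop("ill-conditioned p(r) inversion at given lambda")
    lam_used <- lambda
  } else {
    lams <- logspace(1e-10, 1e2, 25)
    sols <- lapply(lams, solve_l)
    okl <- !vapply(sols, is.null, logical(1))
    if (!any(okl)) stop("ill-conditioned p(r) inversion: all weights failed")
    lams <- lams[okl]; sols <- sols[okl]
    chis <- vapply(sols, `[[`, numeric(1), "chi2")
    target <- min(chis) * 1.10 + 1e-12
    pick <- max(which(chis <= target))
    sol <- sols[[pick]]; lam_used <- lams[pick]
  }
  p_full <- c(0, sol$p, 0)
  ip <- sum(p_full) * dr
  if (ip <= 0) stop("ill-conditioned p(r) inversion: non-positive integral")
  rg2 <- sum(r^2 * p_full) * dr / (2 * ip)
  structure(list(r = r, p = p_full, d_max = d_max, rg_real = sqrt(rg2),
                 i0 = ip, lambda = lam_used, chi2_reduced = sol$chi2),
            class = "pofr")
}

#' @export
print.pofr <- function(x, ...) {
  cat(sprintf("p(r): D_max = %.2f nm, real-space Rg = %.3f nm (lambda = %.3g)\n",
              x$d_max, x$rg_real, x$lambda))
  invisible(x)
}

#' Dimensionless Kratky transform
#'
#' Returns Q^2 I(Q) / I(0) versus Q.  A single bell shape returning to
#' baseline indicates a compact globular scatterer; shoulders indicate a
#' multi-domain architecture such as an unstacked dimer.
#'
#' @param profile A [saxs_profile()].
#' @param i0 Forward intensity I(0); defaults to the I(0) of an automatic
#'   Guinier fit of the profile.
#' @return A data.frame with columns `q` and `kratky`.
#' @export
kratky <- function(profile, i0 = NULL) {
  stopifnot(inherits(profile, "saxs_profile"))
  if (is.null(i0)) i0 <- guinier_rg(profile)$i0
  if (!is_number(i0) || i0 <= 0) stop("missing or invalid I(0)")
  data.frame(q = profile$q, kratky = profile$q^2 * profile$intensity / i0)
}

#' Count Kratky features (maxima and shoulders)
#'
#' Counts the structural features of a Kratky curve below `q_max`: local
#' maxima plus shoulders, the latter detected as positive local minima of
#' the first derivative that dip below half of the neighbouring derivative
#' level (a plateau on a rising flank).  A compact globular scatterer gives
#' one feature (a single bell); a two-domain dimer gives two.
#'
#' @param k A data.frame from [kratky()].
#' @param q_max Analysis limit (nm^-1); features beyond the first form-factor
#'   oscillation are not structural.
#' @param recovery_ratio How much the (log-Q) derivative must rise again
#'   after a positive local minimum for the slowdown to count as a shoulder.
#' @return Integer feature count.
#' @export
kratky_features <- function(k, q_max = 3, recovery_ratio = 1.25) {
  sel <- k$q <= q_max
  q <- k$q[sel]; y <- k$kratky[sel]
  if (length(y) < 15) return(0L)
  w <- 5
  ys <- stats::filter(y, rep(1 / w, w), sides = 2)
  keep <- !is.na(ys)
  q <- q[keep]; y <- as.numeric(ys[keep])
  # local maxima with 5% prominence
  imax <- which(diff(sign(diff(y))) == -2) + 1
  imax <- imax[y[imax] > 0.05 * max(y)]
  # shoulders: a positive local minimum of dK/dlogQ followed by a
  # substantial recovery - a slowdown on a rising flank
  dy <- diff(y) / diff(log(q))
  dys <- stats::filter(dy, rep(1 / w, w), sides = 2)
  dys <- as.numeric(dys[!is.na(dys)])
  imin <- which(diff(sign(diff(dys))) == 2) + 1
  n_sh <- 0L
  for (i in imin) {
    if (dys[i] <= 0) next
    if (max(dys[i:length(dys)]) > recovery_ratio * dys[i]) n_sh <- n_sh + 1L
  }
  length(imax) + n_sh
}
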