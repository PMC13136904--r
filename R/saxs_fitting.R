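#' Fit the stacked fraction by a two-state linear combination
#'
#' Fits an experimental (or synthetic) profile as
#' \deqn{I(Q) = A\,(p_{st} I_0(Q) + (1 - p_{st}) I_\infty(Q)) + bckg}
#' where I_0 and I_infinity are the simulated intensities of the fully
#' stacked (T* = 0) and stacking-free (T* = infinity) reference ensembles.
#' The fit is reparametrized as a0 = A*p_st, a1 = A*(1 - p_st), solved by
#' weighted linear least squares with non-negativity on a0 and a1 (an exact
#' active-set step), which constrains p_st to [0, 1] by construction.
#'
#' @param i_exp Target [saxs_profile()]; its sigma (if present) provides the
#'   1/sigma^2 weights.
#' @param i0 Simulated fully stacked reference profile.
#' @param i_inf Simulated stacking-free reference profile.
#' @param sim_sigma Optional Monte-Carlo uncertainty of the simulated
#'   curves, added in quadrature to the experimental sigma.
#' @return Object of class `"pst_fit"`: `p_st`, `p_st_se`, `A`, `A_se`,
#'   `bckg`, `bckg_se`, `chi2_reduced`, `at_boundary`, `n_points`.
#' @export
fit_pst <- function(i_exp, i0, i_inf, sim_sigma = NULL) {
  stopifnot(inherits(i_exp, "saxs_profile"), inherits(i0, "saxs_profile"),
            inherits(i_inf, "saxs_profile"))
  q <- i_exp$q
  lo <- max(min(i0$q), min(i_inf$q)); hi <- min(max(i0$q), max(i_inf$q))
  keep <- q >= lo & q <= hi
  if (sum(keep) < 5) stop("fewer than 5 common Q points")
  q <- q[keep]
  y <- i_exp$intensity[keep]
  b0 <- interp_profile(i0, q)
  b1 <- interp_profile(i_inf, q)
  sig <- if (is.null(i_exp$sigma)) rep(1, length(q)) else i_exp$sigma[keep]
  if (!is.null(sim_sigma)) sig <- sqrt(sig^2 + sim_sigma^2)
  # collinearity guard
  X <- cbind(i0 = b0, iinf = b1, bckg = 1) / sig
  sv <- svd(X, nu = 0, nv = 0)$d
  if (sv[3] <= 0 || sv[1] / sv[3] > 1e10)
    stop("basis indistinguishable: I0 and I_inf are collinear on this grid")
  yw <- y / sig

  solve_ls <- function(cols) {
    Xs <- X[, cols, drop = FALSE]
    cf <- qr.solve(Xs, yw)
    full <- setNames(numeric(3), colnames(X))
    full[cols] <- cf
    full
  }
  cf <- solve_ls(colnames(X))
  at_boundary <- FALSE
  if (cf["i0"] < 0 || cf["iinf"] < 0) {
    at_boundary <- TRUE
    drop_col <- if (cf["i0"] < cf["iinf"]) "i0" else "iinf"
    cf <- solve_ls(setdiff(colnames(X), drop_col))
    cf[drop_col] <- 0
    if (any(cf[c("i0", "iinf")] < 0))
      stop("degenerate fit: both mixture coefficients pinned at zero")
  }
  a0 <- cf[["i0"]]; a1 <- cf[["iinf"]]; bckg <- cf[["bckg"]]
  res <- yw - X %*% cf
  dof <- length(q) - (3 - at_boundary)
  chi2_red <- sum(res^2) / max(dof, 1)
  # covariance of the active parameters, scaled by reduced chi2
  act <- c("i0", "iinf", "bckg")
  if (at_boundary) act <- names(cf)[cf != 0 | names(cf) == "bckg"]
  Xa <- X[, act, drop = FALSE]
  cov <- chi2_red * solve(crossprod(Xa))
  se <- setNames(numeric(3), colnames(X))
  se[act] <- sqrt(diag(cov))
  A <- a0 + a1
  p_st <- if (A > 0) a0 / A else NA_real_
  # delta method: grad p_st = (a1, -a0)/A^2
  p_se <- NA_real_
  if (A > 0 && all(c("i0", "iinf") %in% act)) {
    g <- c(a1, -a0) / A^2
    p_se <- sqrt(drop(t(g) %*% cov[c("i0", "iinf"), c("i0", "iinf")] %*% g))
  } else if (A > 0) {
    p_se <- se[["i0"]] / A + se[["iinf"]] / A  # boundary: conservative
  }
  A_se <- if (all(c("i0", "iinf") %in% act)) {
    sqrt(sum(cov[c("i0", "iinf"), c("i0", "iinf")]))
  } else sqrt(sum(se[c("i0", "iinf")]^2))
  structure(list(p_st = p_st, p_st_se = p_se, A = A, A_se = A_se,
                 bckg = bckg, bckg_se = se[["bckg"]],
                 chi2_reduced = chi2_red, at_boundary = at_boundary,
                 n_points = length(q)),
            class = "pst_fit")
}

#' @export
print.pst_fit <- function(x, ...) {
  cat(sprintf("p_st = %.3f +/- %.3f (A = %.3g, bckg = %.3g, chi2_red = %.3g)%s\n",
              x$p_st, x$p_st_se, x$A, x$bckg, x$chi2_reduced,
              if (x$at_boundary) " [boundary]" else ""))
  invisible(x)
}

# shape-preserving interpolation of a profile onto a new grid
interp_profile <- function(profile, q_new) {
  f <- splinefun(profile$q, profile$intensity, method = "monoH.FC")
  f(q_new)
}

#' Intensity ratio of two SAXS profiles
#'
#' Forms R(Q) = I_T(Q) / I_T+L(Q) on the numerator grid with first-order
#' uncertainty propagation.  Points where the denominator is not positive or
#' where the propagated relative error exceeds `rel_err_max` are dropped
#' (the number dropped is reported as an attribute).
#'
#' @param i_t Numerator profile (e.g. the free dimer).
#' @param i_tl Denominator profile (e.g. the ligand-bound dimer);
#'   interpolated onto the numerator grid.
#' @param rel_err_max Maximum relative error retained (default 50%).
#' @return A data.frame with columns `q`, `ratio`, `sigma`, carrying
#'   attribute `n_dropped`.
#' @export
compute_ratio <- function(i_t, i_tl, rel_err_max = 0.5) {
  stopifnot(inherits(i_t, "saxs_profile"), inherits(i_tl, "saxs_profile"))
  lo <- min(i_tl$q); hi <- max(i_tl$q)
  keep <- i_t$q >= lo & i_t$q <= hi
  q <- i_t$q[keep]
  num <- i_t$intensity[keep]
  den <- interp_profile(i_tl, q)
  sd_num <- if (is.null(i_t$sigma)) rep(0, length(q)) else i_t$sigma[keep]
  sd_den <- if (is.null(i_tl$sigma)) rep(0, length(q)) else {
    approx(i_tl$q, i_tl$sigma, q, rule = 2)$y
  }
  ok <- den > 0
  ratio <- num[ok] / den[ok]
  rel <- sqrt((sd_num[ok] / num[ok])^2 + (sd_den[ok] / den[ok])^2)
  rel[!is.finite(rel)] <- Inf
  good <- rel <= rel_err_max
  out <- data.frame(q = q[ok][good], ratio = ratio[good],
                    sigma = abs(ratio[good]) * pmax(rel[good], 1e-12))
  attr(out, "n_dropped") <- length(q) - nrow(out)
  out
}

ratio_model <- function(q, r_t, r_tl, k) {
  k * (1 + sinc(q * r_t)) / (1 + sinc(q * r_tl))
}

#' Simultaneous fit of intensity-ratio curves
#'
#' Fits one or more ratio datasets with
#' \deqn{R(Q) = k \frac{1 + \sin(Q R_{cm,T})/(Q R_{cm,T})}
#'                    {1 + \sin(Q R_{cm,T+L})/(Q R_{cm,T+L})}}
#' where the free-dimer distance R_cm_T is shared across the whole dataset
#' and each curve has its own bound-dimer distance R_cm_T+L and scale k
#' (optionally one shared k).  Weighted Levenberg-Marquardt with multiple
#' starting points; parameter uncertainties from the Jacobian at the
#' optimum, scaled by the reduced chi-squared.
#'
#' @param ratio_curves A data.frame from [compute_ratio()] or a list of
#'   them; columns `q`, `ratio`, and optionally `sigma`.
#' @param share_k Share the scale factor k across datasets.
#' @param r_upper Sanity upper bound for distances (nm); default
#'   2*H + 2*R_HC of the default geometry.
#' @param n_starts Number of multi-start initializations.
#' @return Object of class `"ratio_fit"`: `r_cm_t`, `r_cm_t_se`,
#'   data.frame `per_dataset` (`r_cm_tl`, `r_cm_tl_se`, `k`, `k_se`),
#'   `chi2_reduced`, `n_points`.
#' @export
fit_ratio <- function(ratio_curves, share_k = FALSE, r_upper = 2 * 2.64 + 2 * 1.26,
                      n_starts = 8) {
  if (is.data.frame(ratio_curves)) ratio_curves <- list(ratio_curves)
  nd <- length(ratio_curves)
  if (nd < 1) stop("need at least one ratio dataset")
  ratio_curves <- lapply(ratio_curves, function(d) {
    stopifnot(all(c("q", "ratio") %in% names(d)))
    if (is.null(d$sigma)) d$sigma <- rep(1, nrow(d))
    d
  })
  nk <- if (share_k) 1 else nd
  # parameters: r_t, r_tl[1..nd], k[1..nk]
  unpack <- function(p) {
    list(r_t = p[1], r_tl = p[1 + seq_len(nd)],
         k = if (share_k) rep(p[1 + nd + 1], nd) else p[1 + nd + seq_len(nd)])
  }
  resid_fn <- function(p) {
    pr <- unpack(p)
    unlist(lapply(seq_len(nd), function(i) {
      d <- ratio_curves[[i]]
      (ratio_model(d$q, pr$r_t, pr$r_tl[i], pr$k[i]) - d$ratio) / d$sigma
    }))
  }
  k0 <- vapply(ratio_curves, function(d) mean(d$ratio[seq_len(min(5, nrow(d)))]),
               numeric(1))
  lower <- c(0.3, rep(0.3, nd), rep(1e-6, nk))
  upper <- c(r_upper, rep(r_upper, nd), rep(Inf, nk))
  r_starts <- seq(0.25 * r_upper, 0.75 * r_upper, length.out = max(2, ceiling(n_starts / 2)))
  shrink <- c(0.85, 1.0)
  best <- NULL
  for (r0 in r_starts) for (sh in shrink) {
    p0 <- c(r0, rep(r0 * sh, nd), if (share_k) mean(k0) else k0)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_fn, lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(fit$fvec^2)
    if (is.null(best) || ssr < best_ssr) { best <- fit; best_ssr <- ssr }
  }
  if (is.null(best)) stop("ratio fit failed to converge from any start")
  p <- best$par
  n_tot <- sum(vapply(ratio_curves, nrow, integer(1)))
  dof <- max(n_tot - length(p), 1)
  chi2_red <- best_ssr / dof
  # covariance via the Jacobian
  J <- best$hessian  # nls.lm stores J^T J approximation in $hessian
  cov <- tryCatch(chi2_red * solve(J), error = function(e) matrix(NA, length(p), length(p)))
  se <- sqrt(pmax(diag(cov), 0))
  pr <- unpack(p)
  se_u <- unpack(se)
  per <- data.frame(r_cm_tl = pr$r_tl, r_cm_tl_se = se_u$r_tl,
                    k = pr$k, k_se = se_u$k)
  structure(list(r_cm_t = pr$r_t, r_cm_t_se = se_u$r_t, per_dataset = per,
                 chi2_reduced = chi2_red, n_points = n_tot,
                 share_k = share_k, converged = best$info %in% 1:4),
            class = "ratio_fit")
}

#' @export
print.ratio_fit <- function(x, ...) {
  cat(sprintf("Ratio fit: shared R_cm_T = %.3f +/- %.3f nm, chi2_red = %.3g\n",
              x$r_cm_t, x$r_cm_t_se, x$chi2_reduced))
  print(x$per_dataset)
  invisible(x)
}

#' Grid search over cylinder dimensions
#'
#' Explores cylinder radii `r_hc` (default 1.18-1.26 nm in 0.01 nm steps);
#' for each radius, `n_h` heights are examined in `h_step` (default 0.06 nm)
#' increments centered on the height that keeps the single-cylinder radius
#' of gyration constant, H(R_HC) = sqrt(12 (Rg_ref^2 - R_HC^2/2)).  Every
#' candidate geometry is simulated at T* = 0 and T* = infinity, the target
#' profile is fitted by [fit_pst()], and the candidate with the lowest
#' reduced chi-squared wins.
#'
#' @param target Target [saxs_profile()].
#' @param rg_ref Reference single-cylinder Rg (nm) for the constant-Rg
#'   centering (typically the Guinier Rg of the monomer analogue).
#' @param r_hc Candidate radii (nm).
#' @param h_step Height increment (nm).
#' @param n_h Number of heights per radius (odd; centered).
#' @param mc A [simulation_config()] used for every candidate (reduced
#'   sizes are appropriate).
#' @param points_per_cylinder Debye decoration density.
#' @param patches A [patch_spec()].
#' @return Object of class `"geometry_search"`: `best` geometry,
#'   `table` (per-candidate chi2), and the grid description.
#' @export
grid_search_geometry <- function(target, rg_ref,
                                 r_hc = seq(1.18, 1.26, by = 0.01),
                                 h_step = 0.06, n_h = 3,
                                 mc = simulation_config(n_dimers = 150,
                                                        n_thermalization = 200,
                                                        n_snapshots = 5),
                                 points_per_cylinder = 50,
                                 patches = patch_spec()) {
  stopifnot(inherits(target, "saxs_profile"), n_h >= 1)
  offs <- h_step * (seq_len(n_h) - (n_h + 1) / 2)
  rows <- list()
  for (r in r_hc) {
    hc2 <- 12 * (rg_ref^2 - r^2 / 2)
    if (hc2 <= 0) next
    h_center <- sqrt(hc2)
    for (dh in offs) {
      H <- h_center + dh
      if (H <= 0) next
      geom <- cylinder_geometry(radius = r, height = H)
      chi2 <- tryCatch({
        cfg0 <- mc; cfg0$tstar <- 0
        cfgI <- mc; cfgI$tstar <- Inf; cfgI$seed <- mc$seed + 1L
        t0 <- suppressWarnings(run_mc(cfg0, geom, patches))
        tI <- suppressWarnings(run_mc(cfgI, geom, patches))
        i0 <- simulate_intensity(t0, target$q, points_per_cylinder)
        iI <- simulate_intensity(tI, target$q, points_per_cylinder)
        fit_pst(target, i0, iI)$chi2_reduced
      }, error = function(e) NA_real_)
      rows[[length(rows) + 1]] <- data.frame(r_hc = r, height = H, chi2 = chi2)
    }
  }
  tab <- do.call(rbind, rows)
  if (all(is.na(tab$chi2))) stop("all candidate simulations failed")
  best_row <- tab[which.min(tab$chi2), ]
  structure(list(best = cylinder_geometry(best_row$r_hc, best_row$height),
                 table = tab,
                 grid = list(r_hc = r_hc, h_step = h_step, n_h = n_h,
                             rg_ref = rg_ref)),
            class = "geometry_search")
}
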