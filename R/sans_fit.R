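# SANS curve fitting: low-q power-law characterization, bounded
# Levenberg-Marquardt single-curve and simultaneous multi-contrast fits,
# and the contrast-variation water-fraction estimator.
#
# The joint fit shares the particle geometry (and power-law exponent)
# across contrasts while the particle SLD, power-law amplitude and
# background float per curve; `scale` is held fixed (it is exactly
# degenerate with the SLD contrast) and the particle volume fraction,
# charge and screening enter as fixed nuisance parameters. Each per-curve
# particle SLD is bounded above by its solvent SLD to select the physical
# hydrogenous-particle branch of the contrast sign ambiguity.

FITTABLE <- c("radius", "length", "sld_particle", "phi", "charge",
              "screening", "power_amp", "power_exp", "scale", "background")

fit_bounds <- function(name, sld_solvent = NULL) {
  switch(name,
    radius = c(1, 500), length = c(2, 5000),
    sld_particle = c(-1, if (is.null(sld_solvent)) 8 else sld_solvent),
    phi = c(1e-6, 0.5), charge = c(0, 200), screening = c(1, 1e4),
    power_amp = c(0, 1), power_exp = c(2, 5), scale = c(1e-6, 1e3),
    background = c(0, 1))
}

effective_sigma <- function(curve) {
  s <- curve$sigma
  bad <- !is.finite(s) | s <= 0
  s[bad] <- pmax(1e-4 * abs(curve$I[bad]), 1e-8)
  s
}

#' Low-q power-law exponent of a SANS curve
#'
#' Weighted least-squares slope of log I vs log q inside the window,
#' negated. The default window (0.006--0.017 1/A) targets the initial
#' surface-scattering decay of large aggregates, for which exponents
#' between 3 and 4 are expected; a fitted exponent below 1 triggers a
#' warning (flat curve: no power-law regime).
#'
#' @param curve a `SANSCurve`.
#' @param q_window `c(qmin, qmax)`, 1/A.
#' @return list with `exponent`, `se`, `amplitude` (cm^-1 A^-n),
#'   `n_points`.
#' @export
fit_powerlaw_exponent <- function(curve, q_window = c(0.006, 0.017)) {
  w <- curve$q >= q_window[1] & curve$q <= q_window[2]
  if (sum(w) < 4) stop("fewer than 4 points in the power-law window")
  if (any(curve$I[w] <= 0)) stop("non-positive intensities in the window")
  sig <- effective_sigma(curve)[w]
  # var(log I) ~ (sigma / I)^2
  wt <- (curve$I[w] / sig)^2
  fit <- stats::lm(log(curve$I[w]) ~ log(curve$q[w]), weights = wt)
  n <- -unname(coef(fit)[2])
  se <- sqrt(diag(vcov(fit)))[2]
  if (n < 1) warning("fitted exponent ", signif(n, 3),
                     " is outside the surface-scattering band; flat curve?")
  list(exponent = n, se = unname(se), amplitude = exp(unname(coef(fit)[1])),
       n_points = sum(w))
}

# finite-difference Jacobian of a residual function at a point
fd_jacobian <- function(fn, par, eps = 1e-6) {
  r0 <- fn(par)
  J <- matrix(NA_real_, length(r0), length(par))
  for (j in seq_along(par)) {
    h <- eps * max(abs(par[j]), 1)
    pj <- par; pj[j] <- pj[j] + h
    J[, j] <- (fn(pj) - r0) / h
  }
  J
}

# bounded LM with multi-start; early-accepts a start that converges with
# reduced chi2 below 2
lm_multistart <- function(resid_fn, init, lower, upper, n_starts = 5,
                          seed = 1, n_obs = NULL, n_par = length(init)) {
  best <- NULL
  jitters <- with_seed(seed, {
    lapply(seq_len(n_starts), function(s) {
      if (s == 1) rep(1, length(init))
      else exp(rnorm(length(init), sd = 0.2))
    })
  })
  for (s in seq_len(n_starts)) {
    p0 <- init * jitters[[s]]
    p0[init == 0] <- init[init == 0]   # multiplicative jitter skips zeros
    p0 <- pmin(pmax(p0, lower), upper)
    res <- tryCatch(
      minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(res)) next
    chi2 <- sum(res$fvec^2)
    cand <- list(par = res$par, chi2 = chi2,
                 converged = res$info %in% 1:4, info = res$info)
    if (is.null(best) || cand$chi2 < best$chi2) best <- cand
    dof <- max((if (is.null(n_obs)) length(res$fvec) else n_obs) - n_par, 1)
    if (cand$converged && cand$chi2 / dof < 2) break
  }
  if (is.null(best)) stop("all optimizer starts failed")
  best
}

finalize_fit <- function(resid_fn, best, n_par) {
  r <- resid_fn(best$par)
  dof <- max(length(r) - n_par, 1)
  redchi2 <- sum(r^2) / dof
  J <- fd_jacobian(resid_fn, best$par)
  # condition and invert in column-scaled space (parameters span many
  # orders of magnitude)
  cn <- sqrt(colSums(J^2))
  sing <- any(cn == 0) || !all(is.finite(cn))
  cov <- matrix(NA_real_, n_par, n_par)
  if (!sing) {
    Js <- sweep(J, 2, cn, `/`)
    JtJ <- crossprod(Js)
    if (rcond(JtJ) < 1e-10) sing <- TRUE
    else {
      covs <- solve(JtJ) * redchi2
      cov <- covs / tcrossprod(cn)
    }
  }
  se <- sqrt(pmax(diag(cov), 0))
  names(se) <- names(best$par)
  list(estimates = best$par, se = se, redchi2 = redchi2,
       converged = best$converged && !sing, singular = sing,
       chi2 = sum(r^2), dof = dof)
}

#' Fit the composite SANS model to a single curve
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) minimising
#' `sum(((I_model - I) / sigma)^2)`. Parameters named in `fixed` are held
#' at their `init` values; the defaults fix the nuisance interaction
#' parameters and the overall scale (degenerate with the SLD contrast).
#'
#' @param curve a `SANSCurve`.
#' @param init a [sans_model_params()] list of starting values.
#' @param fixed character vector of parameter names to hold.
#' @param n_starts jittered multi-starts (first start = `init`).
#' @param seed RNG seed for the start jitter.
#' @return a `FitResult`: list with `estimates`, `se` (1-sigma, from the
#'   Jacobian at the optimum), `redchi2`, `converged`, `singular`,
#'   `params` (full parameter list at the optimum).
#' @export
fit_single_curve <- function(curve, init,
                             fixed = c("phi", "charge", "screening",
                                       "scale"),
                             n_starts = 5, seed = 1) {
  init <- validate_sans_params(init)
  sig <- effective_sigma(curve)
  free <- setdiff(FITTABLE, fixed)
  if (!length(free)) stop("no free parameters")
  p0 <- unlist(init[free])
  lower <- vapply(free, function(n) fit_bounds(n, init$sld_solvent)[1],
                  numeric(1))
  upper <- vapply(free, function(n) fit_bounds(n, init$sld_solvent)[2],
                  numeric(1))
  resid_fn <- function(par) {
    p <- init
    p[free] <- as.list(par)
    (composite_intensity(curve$q, p) - curve$I) / sig
  }
  best <- lm_multistart(resid_fn, p0, lower, upper, n_starts, seed)
  out <- finalize_fit(resid_fn, best, length(p0))
  p_opt <- init; p_opt[free] <- as.list(best$par)
  out$params <- p_opt
  class(out) <- "FitResult"
  out
}

#' @export
print.FitResult <- function(x, ...) {
  cat("FitResult:", if (x$converged) "converged" else "NOT converged",
      sprintf("(reduced chi2 = %.3g)\n", x$redchi2))
  est <- data.frame(estimate = x$estimates, se = x$se)
  print(signif(est, 4))
  invisible(x)
}

#' Simultaneous fit of a multi-contrast SANS series
#'
#' One joint chi-square over all curves: the parameters in `shared` (the
#' particle geometry, and the aggregate power-law exponent) take a single
#' value across contrasts; those in `per_curve` float independently per
#' curve; everything else is held at `init`. Per-curve particle SLDs are
#' reported alongside their solvent SLDs, ready for
#' [water_fraction_from_slds()].
#'
#' @param series a `ContrastSeries` (or list of >= 2 `SANSCurve`s with
#'   distinct `d2o_fraction` attributes).
#' @param init a [sans_model_params()] list of starting values
#'   (`sld_particle` is re-initialised per curve from its solvent unless
#'   supplied); `NULL` for defaults.
#' @param shared,per_curve parameter-name partition of the free
#'   parameters.
#' @param n_starts,seed multi-start control.
#' @return a `FitResult` with additional `per_curve` data frame
#'   (`d2o_fraction`, `sld_solvent`, `sld_particle`, `se`).
#' @export
fit_contrast_series <- function(series, init = NULL,
                                shared = c("radius", "length", "power_exp"),
                                per_curve = c("sld_particle", "power_amp",
                                              "background"),
                                n_starts = 5, seed = 1) {
  curves <- if (inherits(series, "ContrastSeries")) series$curves else series
  nc <- length(curves)
  if (nc < 2) stop("need at least 2 contrast curves for a joint fit")
  d2o <- vapply(curves, function(cu) attr(cu, "d2o_fraction"), numeric(1))
  if (anyNA(d2o)) stop("every curve needs a d2o_fraction attribute")
  if (anyDuplicated(d2o)) stop("D2O fractions must be distinct")
  if (length(intersect(shared, per_curve)))
    stop("shared and per_curve overlap")
  if (is.null(init)) init <- sans_model_params(power_amp = 1e-6,
                                               background = 0.005)
  init <- validate_sans_params(init)
  sld_solv <- solvent_sld(d2o)

  free_names <- c(shared,
                  unlist(lapply(seq_len(nc), function(i)
                    paste0(per_curve, ".", i))))
  p0 <- c(unlist(init[shared]),
          unlist(lapply(seq_len(nc), function(i) {
            v <- unlist(init[per_curve])
            if ("sld_particle" %in% per_curve)
              v["sld_particle"] <- sld_solv[i] - 2   # start on the physical branch
            setNames(v, paste0(per_curve, ".", i))
          })))
  lower <- upper <- numeric(length(p0))
  for (j in seq_along(p0)) {
    base <- sub("\\.[0-9]+$", "", free_names[j])
    ic <- suppressWarnings(as.integer(sub("^.*\\.", "", free_names[j])))
    b <- fit_bounds(base, if (base == "sld_particle") sld_solv[ic] else NULL)
    lower[j] <- b[1]; upper[j] <- b[2]
  }

  sigs <- lapply(curves, effective_sigma)
  resid_fn <- function(par) {
    names(par) <- free_names
    unlist(lapply(seq_len(nc), function(i) {
      p <- init
      p$sld_solvent <- sld_solv[i]
      p[shared] <- as.list(par[shared])
      p[per_curve] <- as.list(par[paste0(per_curve, ".", i)])
      (composite_intensity(curves[[i]]$q, p) - curves[[i]]$I) / sigs[[i]]
    }))
  }
  names(p0) <- free_names
  best <- lm_multistart(resid_fn, p0, lower, upper, n_starts, seed)
  out <- finalize_fit(resid_fn, best, length(p0))
  names(out$estimates) <- free_names
  est <- out$estimates
  pc <- data.frame(
    d2o_fraction = d2o,
    sld_solvent = sld_solv,
    sld_particle = if ("sld_particle" %in% per_curve)
      unname(est[paste0("sld_particle.", seq_len(nc))]) else
        rep(init$sld_particle, nc),
    se = if ("sld_particle" %in% per_curve)
      unname(out$se[paste0("sld_particle.", seq_len(nc))]) else NA_real_)
  out$per_curve <- pc
  out$shared <- shared
  class(out) <- "FitResult"
  out
}

#' Water volume fraction from a contrast-variation SLD regression
#'
#' The particle SLD of a water-swollen particle is linear in the solvent
#' SLD: `SLD_p = phi_water * SLD_s + (1 - phi_water) * SLD_dry`. An
#' ordinary least-squares regression of fitted particle SLDs on their
#' solvent SLDs therefore estimates `phi_water` as the slope and the
#' dry-material SLD as `intercept / (1 - slope)`.
#'
#' @param particle_slds fitted particle SLDs (1e-6 A^-2), one per
#'   contrast.
#' @param solvent_slds matching solvent SLDs (distinct).
#' @return a `WaterFractionResult`: list with `phi_water` (clipped to
#'   `[0, 1]`, `clipped` flag), `sld_dry`, `r_squared`, `slope_se`,
#'   `n_points`.
#' @export
water_fraction_from_slds <- function(particle_slds, solvent_slds) {
  if (length(particle_slds) != length(solvent_slds) ||
      length(particle_slds) < 2)
    stop("need >= 2 paired SLD values")
  if (length(unique(solvent_slds)) < 2)
    stop("solvent SLDs must be distinct")
  if (length(particle_slds) == 2)
    warning("two points: exact interpolation, no residual degrees of freedom")
  fit <- stats::lm(particle_slds ~ solvent_slds)
  slope <- unname(coef(fit)[2]); icpt <- unname(coef(fit)[1])
  clipped <- slope < 0 || slope > 1
  phi_w <- min(max(slope, 0), 1)
  # r^2 and slope s.e. computed directly (summary.lm warns on exact fits)
  n_pts <- length(particle_slds)
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((particle_slds - mean(particle_slds))^2)
  r2 <- if (n_pts > 2) 1 - ss_res / ss_tot else 1
  se <- if (n_pts > 2)
    sqrt(ss_res / (n_pts - 2) /
           sum((solvent_slds - mean(solvent_slds))^2)) else NA_real_
  structure(list(phi_water = phi_w,
                 sld_dry = if (abs(1 - slope) > 1e-9) icpt / (1 - slope)
                 else NA_real_,
                 r_squared = r2, slope_se = unname(se), slope_raw = slope,
                 clipped = clipped, n_points = length(particle_slds)),
            class = "WaterFractionResult")
}
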