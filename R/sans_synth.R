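# Synthetic SANS curves, contrast series and titration tables.

#' Default experimental q grid
#'
#' Logarithmically spaced grid over 0.0057--0.32 1/A (the two-configuration
#' pinhole-SANS range the analyses assume).
#'
#' @param n number of points.
#' @return numeric vector, 1/A.
#' @export
default_q_grid <- function(n = 120) {
  exp(seq(log(0.0057), log(0.32), length.out = n))
}

new_sans_curve <- function(q, I, sigma, d2o_fraction = NA_real_) {
  out <- data.frame(q = q, I = I, sigma = sigma)
  structure(out, class = c("SANSCurve", "data.frame"),
            d2o_fraction = d2o_fraction)
}

#' Simulate a noisy SANS curve from the composite model
#'
#' Evaluates [composite_intensity()] on the q grid and adds zero-mean
#' Gaussian noise with standard deviation `relative_noise * I`; the same
#' sigma is recorded as the uncertainty column. `relative_noise = 0`
#' returns the model exactly (sigma column zero).
#'
#' @param params a [sans_model_params()] list.
#' @param q strictly positive, strictly increasing q grid (1/A).
#' @param relative_noise fractional noise level (>= 0).
#' @param seed integer RNG seed.
#' @param d2o_fraction solvent D2O volume fraction tag carried on the
#'   curve.
#' @return a `SANSCurve` data frame: `q`, `I` (cm^-1), `sigma` (cm^-1).
#' @export
simulate_sans_curve <- function(params, q = default_q_grid(),
                                relative_noise = 0.02, seed = 1,
                                d2o_fraction = NA_real_) {
  if (any(q <= 0) || any(diff(q) <= 0))
    stop("q grid must be strictly positive and increasing")
  if (relative_noise < 0) stop("relative_noise must be >= 0")
  I0 <- composite_intensity(q, params)
  sigma <- relative_noise * I0
  I <- if (relative_noise > 0)
    with_seed(seed, I0 + rnorm(length(q), sd = sigma)) else I0
  new_sans_curve(q, I, sigma, d2o_fraction)
}

#' Presets for the contrast-variation study conditions
#'
#' `"pH2"`: helical chains -- cylinder radius 13 A, length 75 A, internal
#' water fraction 0.51. `"pH8"`: coil chains -- radius 13 A, length 62 A,
#' water fraction 0.59. Shared: dry-polypeptide SLD 1.8e-6 A^-2, particle
#' volume fraction 0.005, effective charge 20 e, Debye length 30 A,
#' aggregate power law `1e-6 * q^-3.6`.
#'
#' @param name `"pH2"` or `"pH8"`.
#' @return list of generator parameters.
#' @export
contrast_preset <- function(name = c("pH2", "pH8")) {
  name <- match.arg(name)
  base <- list(radius = 13, sld_dry = 1.8, phi = 0.005, charge = 20,
               screening = 30, power_amp = 1e-6, power_exp = 3.6,
               d2o_fractions = c(1, 0.75, 0.5))
  c(base, switch(name,
                 pH2 = list(length = 75, phi_water = 0.51),
                 pH8 = list(length = 62, phi_water = 0.59)))
}

#' Simulate a multi-contrast SANS series
#'
#' One curve per solvent contrast, sharing the particle geometry. The
#' particle SLD at each contrast follows the swelling rule
#' `phi_water * SLD_solvent + (1 - phi_water) * sld_dry`, which is what the
#' contrast-variation regression later inverts. The flat background rises
#' with the H2O content (incoherent hydrogen scattering).
#'
#' @param geometry list with `radius` and `length` (A).
#' @param phi_water water volume fraction inside the particle, `[0, 1]`.
#' @param sld_dry dry-material SLD (1e-6 A^-2).
#' @param d2o_fractions solvent D2O volume fractions (each in `[0, 1]`,
#'   non-empty).
#' @param relative_noise fractional noise per point.
#' @param seed integer RNG seed.
#' @param q q grid shared by all curves.
#' @param phi,charge,screening,power_amp,power_exp,scale nuisance model
#'   parameters (see [sans_model_params()]).
#' @param preset optional preset name (see [contrast_preset()]); explicit
#'   arguments override preset values.
#' @return a `ContrastSeries`: list with `curves` (list of `SANSCurve`
#'   tagged with D2O fractions) and `truth` (the planted parameters).
#' @export
simulate_contrast_series <- function(geometry = NULL, phi_water = NULL,
                                     sld_dry = NULL,
                                     d2o_fractions = NULL,
                                     relative_noise = 0.02, seed = 1,
                                     q = default_q_grid(),
                                     phi = 0.005, charge = 20,
                                     screening = 30, power_amp = 1e-6,
                                     power_exp = 3.6, scale = 1,
                                     preset = NULL) {
  if (!is.null(preset)) {
    p <- contrast_preset(preset)
    if (is.null(geometry)) geometry <- list(radius = p$radius, length = p$length)
    if (is.null(phi_water)) phi_water <- p$phi_water
    if (is.null(sld_dry)) sld_dry <- p$sld_dry
    if (is.null(d2o_fractions)) d2o_fractions <- p$d2o_fractions
  }
  if (is.null(geometry)) geometry <- list(radius = 13, length = 75)
  if (is.null(phi_water)) phi_water <- 0.51
  if (is.null(sld_dry)) sld_dry <- 1.8
  if (is.null(d2o_fractions)) d2o_fractions <- c(1, 0.75, 0.5)
  if (length(d2o_fractions) == 0) stop("empty contrast list")
  if (any(d2o_fractions < 0 | d2o_fractions > 1))
    stop("D2O fractions must be in [0, 1]")
  if (phi_water < 0 || phi_water > 1) stop("phi_water must be in [0, 1]")

  curves <- lapply(seq_along(d2o_fractions), function(i) {
    f <- d2o_fractions[i]
    sld_s <- solvent_sld(f)
    params <- sans_model_params(
      radius = geometry$radius, length = geometry$length,
      sld_particle = particle_sld(phi_water, sld_dry, sld_s),
      sld_solvent = sld_s, phi = phi, charge = charge,
      screening = screening, power_amp = power_amp,
      power_exp = power_exp, scale = scale,
      background = 0.001 + 0.01 * (1 - f))
    simulate_sans_curve(params, q, relative_noise,
                        seed = seed + 101L * i, d2o_fraction = f)
  })
  structure(list(curves = curves,
                 truth = list(radius = geometry$radius,
                              length = geometry$length,
                              phi_water = phi_water, sld_dry = sld_dry,
                              phi = phi, charge = charge,
                              screening = screening,
                              power_amp = power_amp, power_exp = power_exp,
                              d2o_fractions = d2o_fractions)),
            class = "ContrastSeries")
}

#' Simulate a pH titration curve
#'
#' Henderson-Hasselbalch protonated fraction
#' `f(pH) = 1 / (1 + 10^(pH - pKa))` plus optional Gaussian noise, clipped
#' to `[0, 1]`.
#'
#' @param pka acid dissociation constant.
#' @param pH_grid pH values (non-empty).
#' @param noise_sd Gaussian noise s.d. on the fraction (>= 0).
#' @param seed integer RNG seed.
#' @return a `TitrationCurve` data frame: `pH`, `fraction`.
#' @export
simulate_titration <- function(pka, pH_grid = seq(2, 9, by = 0.25),
                               noise_sd = 0, seed = 1) {
  if (length(pH_grid) == 0) stop("empty pH grid")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  f <- 1 / (1 + 10^(pH_grid - pka))
  if (noise_sd > 0)
    f <- with_seed(seed, pmin(pmax(f + rnorm(length(f), sd = noise_sd), 0), 1))
  structure(data.frame(pH = pH_grid, fraction = f),
            class = c("TitrationCurve", "data.frame"))
}
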