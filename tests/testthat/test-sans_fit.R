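noiseless_series <- function(preset = "pH2")
  simulate_contrast_series(preset = preset, relative_noise = 0)

test_that("power-law exponent recovery on exact and noisy power laws", {
  q <- default_q_grid()
  exact <- helicoil:::new_sans_curve(q, 2e-7 * q^-3.6, rep(1e-4, length(q)))
  r <- fit_powerlaw_exponent(exact)
  expect_equal(r$exponent, 3.6, tolerance = 1e-6)
  expect_equal(r$amplitude, 2e-7, tolerance = 1e-9)
  # flat curve warns rather than silently accepting
  flat <- helicoil:::new_sans_curve(q, rep(0.01, length(q)),
                                    rep(1e-4, length(q)))
  expect_warning(fit_powerlaw_exponent(flat), "flat")
  expect_error(fit_powerlaw_exponent(exact, q_window = c(0.3, 0.32)),
               "fewer than 4")
})

test_that("single-curve fit recovers geometry from perturbed starts", {
  p_true <- sans_model_params(radius = 13, length = 75, sld_particle = 4.14,
                              sld_solvent = solvent_sld(1),
                              power_amp = 1e-6, background = 0.001)
  cu <- simulate_sans_curve(p_true, relative_noise = 0, d2o_fraction = 1)
  init <- p_true
  init$radius <- 13 * 1.2; init$length <- 75 * 0.8; init$sld_particle <- 3.5
  fit <- fit_single_curve(cu, init, n_starts = 2)
  expect_true(fit$converged)
  expect_equal(unname(fit$estimates["radius"]), 13, tolerance = 0.01)
  expect_equal(unname(fit$estimates["length"]), 75, tolerance = 0.01)
  expect_true(all(fit$se[c("radius", "length")] >= 0))
})

test_that("all-but-background fixed reduces to the weighted mean", {
  q <- default_q_grid(40)
  set.seed(4)
  I <- 0.02 + rnorm(40, sd = 0.001)
  sig <- runif(40, 5e-4, 2e-3)
  flat <- helicoil:::new_sans_curve(q, I, sig)
  init <- sans_model_params(sld_particle = solvent_sld(1), power_amp = 0,
                            background = 0.01, use_sq = FALSE)
  fit <- fit_single_curve(flat, init,
                          fixed = setdiff(helicoil:::FITTABLE, "background"),
                          n_starts = 1)
  expect_equal(unname(fit$estimates["background"]),
               sum(I / sig^2) / sum(1 / sig^2), tolerance = 1e-6)
})

test_that("joint fit shares geometry and recovers planted parameters", {
  fit <- fit_contrast_series(noiseless_series("pH2"), n_starts = 2)
  expect_true(fit$converged)
  expect_equal(unname(fit$estimates["radius"]), 13, tolerance = 0.13)
  expect_equal(unname(fit$estimates["length"]), 75, tolerance = 0.75)
  # per-curve SLDs land on the planted swelling line
  wf <- water_fraction_from_slds(fit$per_curve$sld_particle,
                                 fit$per_curve$sld_solvent)
  expect_equal(wf$phi_water, 0.51, tolerance = 0.01)
  expect_equal(wf$sld_dry, 1.8, tolerance = 0.1)
  expect_gt(wf$r_squared, 0.999)
})

test_that("helical preset fits longer than the coil preset", {
  f2 <- fit_contrast_series(simulate_contrast_series(preset = "pH2",
                                                     relative_noise = 0.02,
                                                     seed = 21), n_starts = 2)
  f8 <- fit_contrast_series(simulate_contrast_series(preset = "pH8",
                                                     relative_noise = 0.02,
                                                     seed = 21), n_starts = 2)
  expect_gt(unname(f2$estimates["length"]), unname(f8$estimates["length"]))
})

test_that("joint fit input validation", {
  ser <- noiseless_series()
  expect_error(fit_contrast_series(ser$curves[1]), "at least 2")
  dup <- ser$curves[c(1, 1)]
  expect_error(fit_contrast_series(dup), "distinct")
  expect_error(fit_contrast_series(ser, shared = c("radius"),
                                   per_curve = c("radius")), "overlap")
})

test_that("water-fraction regression handles exact and degenerate input", {
  solv <- solvent_sld(c(1, 0.75, 0.5))
  part <- 0.51 * solv + 0.49 * 1.8
  wf <- water_fraction_from_slds(part, solv)
  expect_equal(wf$phi_water, 0.51, tolerance = 1e-12)
  expect_equal(wf$sld_dry, 1.8, tolerance = 1e-9)
  expect_equal(wf$r_squared, 1, tolerance = 1e-12)
  expect_false(wf$clipped)
  # slope zero: dry particle
  wf0 <- water_fraction_from_slds(rep(2, 3) + c(0, 1e-12, -1e-12), solv)
  expect_equal(wf0$phi_water, 0, tolerance = 1e-6)
  # two points: exact interpolation with a warning
  expect_warning(wf2 <- water_fraction_from_slds(part[1:2], solv[1:2]),
                 "two points")
  expect_equal(wf2$phi_water, 0.51, tolerance = 1e-12)
  expect_equal(wf2$r_squared, 1)
  # noisy slopes outside [0,1] are clipped and flagged
  wfc <- water_fraction_from_slds(c(0, 4, 9), solv[c(3, 2, 1)] * 1)
  expect_true(wfc$phi_water <= 1 && wfc$clipped)
  expect_error(water_fraction_from_slds(part, rep(3, 3)), "distinct")
  expect_error(water_fraction_from_slds(part[1], solv[1]), ">= 2")
})

test_that("joint chi2 with truly shared parameters beats split fits", {
  ser <- simulate_contrast_series(preset = "pH2", relative_noise = 0.02,
                                  seed = 31)
  joint <- fit_contrast_series(ser, n_starts = 1)
  # independent single-curve fits can only lower the total chi2
  singles <- lapply(ser$curves, function(cu) {
    init <- sans_model_params(radius = 15, length = 60,
                              sld_particle = solvent_sld(attr(cu, "d2o_fraction")) - 2,
                              sld_solvent = solvent_sld(attr(cu, "d2o_fraction")),
                              power_amp = 1e-6, power_exp = 3.6,
                              background = 0.005)
    fit_single_curve(cu, init, n_starts = 1)
  })
  expect_gte(joint$chi2 + 1e-6, sum(vapply(singles, function(f)
    f$chi2, numeric(1))) - 1)
})
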