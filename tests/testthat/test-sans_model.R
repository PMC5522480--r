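test_that("pure-water SLDs follow from the scattering lengths", {
  # derivation: (2 b_X + b_O) fm / 30 A^3, in 1e-6 A^-2
  expect_equal(solvent_sld(1), (2 * 6.671 + 5.803) * 10 / 30,
               tolerance = 1e-12)
  expect_equal(solvent_sld(0), (2 * -3.739 + 5.803) * 10 / 30,
               tolerance = 1e-12)
  expect_equal(solvent_sld(0.5), (solvent_sld(1) + solvent_sld(0)) / 2,
               tolerance = 1e-12)
  expect_equal(round(solvent_sld(1), 2), 6.38)
  expect_equal(round(solvent_sld(0), 2), -0.56)
  expect_error(solvent_sld(1.2), "\\[0, 1\\]")
})

test_that("particle SLD mixes linearly with water content", {
  expect_equal(particle_sld(0, 2, 6), 2)
  expect_equal(particle_sld(1, 2, 6), 6)
  expect_equal(particle_sld(0.5, 2, 6), 4)
  expect_error(particle_sld(1.5, 2, 6), "phi_water")
})

test_that("cylinder form factor has the exact forward limit", {
  R <- 13; L <- 75; dr <- 2.5
  V <- pi * R^2 * L
  expect_equal(cylinder_form_factor(1e-7, R, L, dr), 1e-4 * dr^2 * V,
               tolerance = 1e-8)
  expect_error(cylinder_form_factor(0.1, -1, 75), "geometry")
  expect_error(cylinder_form_factor(-0.1, 13, 75), "q must be")
})

test_that("Gauss-Legendre quadrature matches brute-force integration", {
  R <- 13; L <- 75
  alpha <- seq(1e-7, pi / 2, length.out = 1e6)
  for (q in c(0.02, 0.08, 0.2, 0.32)) {
    k <- sin(q * L * cos(alpha) / 2) / (q * L * cos(alpha) / 2) *
      2 * besselJ(q * R * sin(alpha), 1) / (q * R * sin(alpha))
    brute <- 1e-4 * pi * R^2 * L *
      pracma::trapz(alpha, k^2 * sin(alpha))
    expect_equal(cylinder_form_factor(q, R, L), brute,
                 tolerance = 1e-5, info = paste("q =", q))
  }
})

test_that("fit-range decay and first-minimum position match the oracle", {
  q <- seq(0.017, 0.32, length.out = 300)
  P <- cylinder_form_factor(q, 13, 75)
  # monotone decay across most of the window; a shallow radial minimum
  # sits near q R ~ 3.8
  expect_true(all(diff(P[q <= 0.28]) < 0))
  imin <- which(diff(sign(diff(P))) > 0) + 1
  expect_length(imin, 1)
  # brute-force trapezoidal oracle locates the same minimum
  qf <- seq(0.28, 0.32, length.out = 60)
  alpha <- seq(1e-7, pi / 2, length.out = 2e5)
  Pb <- vapply(qf, function(qq) {
    k <- sin(qq * 75 * cos(alpha) / 2) / (qq * 75 * cos(alpha) / 2) *
      2 * besselJ(qq * 13 * sin(alpha), 1) / (qq * 13 * sin(alpha))
    pracma::trapz(alpha, k^2 * sin(alpha))
  }, numeric(1))
  expect_equal(q[imin], qf[which.min(Pb)], tolerance = 0.01)
})

test_that("PY hard-sphere structure factor limits", {
  q <- seq(0.1, 20, length.out = 50)
  expect_equal(py_hardsphere_sq(q, 1, 0), rep(1, 50))
  # closed-form compressibility limit
  for (phi in c(0.1, 0.2, 0.4))
    expect_equal(py_hardsphere_sq(1e-6, 1, phi),
                 (1 - phi)^4 / (1 + 2 * phi)^2, tolerance = 1e-6)
  # large-q limit
  expect_equal(py_hardsphere_sq(500, 1, 0.2), 1, tolerance = 1e-3)
  expect_error(py_hardsphere_sq(q, 1, 0.8), "phi")
})

test_that("charged spheres suppress low-q structure vs hard spheres", {
  d <- 30; phi <- 0.2
  q <- seq(0.004, 0.6, length.out = 40)
  S_hs <- py_hardsphere_sq(q, d, phi)
  S_ch <- hayter_penfold_sq(q, d, phi, Z = 10, screening = 10,
                            control = list(dr = 2e-3, nr = 16383L,
                                           tol = 1e-8))
  expect_lt(S_ch[1], S_hs[1])
  expect_equal(tail(S_ch, 1), 1, tolerance = 1e-2)
  expect_true(all(S_ch >= 0))
})

test_that("dilute limit and argument checking of the RMSA factor", {
  q <- seq(0.01, 0.5, length.out = 20)
  expect_equal(hayter_penfold_sq(q, 30, 1e-9, Z = 20, screening = 30),
               rep(1, 20))
  S <- hayter_penfold_sq(q, 30, 1e-4, Z = 0, screening = 30,
                         control = list(dr = 2e-3, nr = 16383L, tol = 1e-8))
  expect_equal(S, rep(1, 20), tolerance = 1e-3)
  expect_error(hayter_penfold_sq(q, 30, 0.2, Z = 5, screening = -1),
               "negative screening")
  expect_error(hayter_penfold_sq(q, 30, 0.2, Z = 5), "either")
  expect_error(hayter_penfold_sq(q, 30, 0.2, Z = 5, screening = 30,
                                 ionic_strength = 0.1), "not both")
})

test_that("Debye length conversion is physically calibrated", {
  # 0.1 M 1:1 electrolyte in water at 298 K: ~9.6 A
  expect_equal(debye_length(0.1), 9.6, tolerance = 0.02)
  expect_equal(debye_length(0.01), sqrt(10) * debye_length(0.1),
               tolerance = 1e-6)
})

test_that("composite intensity assembles its terms correctly", {
  q <- seq(0.006, 0.3, length.out = 30)
  # zero contrast, no power law: flat background
  p0 <- sans_model_params(sld_particle = 6.381667, sld_solvent = 6.381667,
                          background = 0.01, power_amp = 0)
  expect_equal(composite_intensity(q, p0), rep(0.01, 30), tolerance = 1e-10)
  # S = 1 limit reduces to scale * phi * P + B
  p1 <- sans_model_params(sld_particle = 4, charge = 0, phi = 1e-9,
                          background = 0.002, power_amp = 0)
  expect_equal(composite_intensity(q, p1),
               1e-9 * cylinder_form_factor(q, 13, 75, 4 - p1$sld_solvent) +
                 0.002, tolerance = 1e-6)
  # linear in scale, monotone in background
  p2 <- sans_model_params(sld_particle = 4, power_amp = 1e-6,
                          background = 0.002)
  I1 <- composite_intensity(q, p2)
  p2b <- p2; p2b$scale <- 2
  I2 <- composite_intensity(q, p2b)
  expect_equal((I2 - 1e-6 * q^-3.6 - 0.002) / (I1 - 1e-6 * q^-3.6 - 0.002),
               rep(2, 30), tolerance = 1e-8)
  p2c <- p2; p2c$background <- 0.004
  expect_equal(composite_intensity(q, p2c) - I1, rep(0.002, 30),
               tolerance = 1e-9)
  expect_error(sans_model_params(phi = 0.8), "phi")
  expect_error(sans_model_params(radius = -2), ">= 0")
})

test_that("preset low-q decay sits in the surface-scattering band", {
  p <- sans_model_params(sld_particle = 4.14, power_amp = 1e-6,
                         background = 0.001)
  q <- exp(seq(log(0.006), log(0.017), length.out = 20))
  I <- composite_intensity(q, p)
  slope <- coef(lm(log(I) ~ log(q)))[[2]]
  expect_gte(slope, -3.7)
  expect_lte(slope, -3.5)
})
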