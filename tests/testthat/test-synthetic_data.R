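test_that("ideal helix places C-alpha exactly on the cylinder", {
  h <- generate_ideal_helix(10, 0.23, 100, 0.15)
  ca <- calpha(h)
  expect_equal(sqrt(rowSums(ca[, 1:2]^2)), rep(0.23, 10), tolerance = 1e-12)
  # closed form: C-alpha 1 and 19 separated axially by 18 * rise
  h36 <- generate_ideal_helix(36, 0.23, 100, 0.15)
  z <- calpha(h36)[, 3]
  expect_equal(z[19] - z[1], 18 * 0.15, tolerance = 1e-12)
  # two-point case: projected angle equals the twist
  h2 <- generate_ideal_helix(2, 0.23, 100, 0.15)
  xy <- calpha(h2)[, 1:2]
  ang <- acos(sum(xy[1, ] * xy[2, ]) /
                (sqrt(sum(xy[1, ]^2)) * sqrt(sum(xy[2, ]^2)))) * 180 / pi
  expect_equal(ang, 100, tolerance = 1e-9)
  expect_error(generate_ideal_helix(10, radius = -1), "non-physical")
  expect_error(generate_ideal_helix(10, twist = 200), "non-physical")
})

test_that("bonded heavy-atom distances stay in the physical band", {
  for (conf in list(generate_ideal_helix(10),
                    generate_random_coil(10, 3))) {
    ca <- calpha(conf)
    steps <- sqrt(rowSums(diff(ca)^2))
    expect_true(all(steps > 0.05 & steps < 0.45))
    expect_true(all(is.finite(conf$xyz)))
  }
})

test_that("self-avoiding coil respects its constraints and seed", {
  c1 <- generate_random_coil(10, 1)
  c2 <- generate_random_coil(10, 1)
  expect_identical(c1$xyz, c2$xyz)
  c50 <- generate_random_coil(50, 7)
  d <- as.matrix(dist(calpha(c50)))
  nonbonded <- abs(row(d) - col(d)) > 1
  expect_gte(min(d[nonbonded]), 0.4)
  # a coil is far from helical
  expect_gt(rmsd_to_ideal_helix(c50), 0.2)
})

test_that("perturbation is exact at zero amplitude and seeded", {
  h <- generate_ideal_helix(10)
  expect_identical(perturb_conformation(h, 0, 1)$xyz, h$xyz)
  p1 <- perturb_conformation(h, 0.02, 42)
  expect_identical(p1$xyz, perturb_conformation(h, 0.02, 42)$xyz)
  expect_false(identical(p1$xyz, perturb_conformation(h, 0.02, 43)$xyz))
  expect_error(perturb_conformation(h, -0.1, 1), "amplitude")
  # noisy helix stays near-helical: empirical envelope over seeds
  r <- vapply(1:30, function(s)
    rmsd_to_ideal_helix(perturb_conformation(h, 0.02, s)), numeric(1))
  expect_true(all(r > 0 & r <= 0.06))
})

test_that("solvation plants the depletion zone and fills the box", {
  h <- generate_ideal_helix(10)
  fr <- solvate(h, box_edge = 5, n_waters = 500, depletion_radius = 0.4,
                seed = 3)
  expect_equal(nrow(fr$water_o), 500)
  expect_equal(nrow(fr$water_h), 1000)
  com <- backbone_com(fr)
  expect_gte(min(helicoil:::min_image_dist(fr$water_o, com, fr$box)), 0.4)
  # O-H geometry (minimum-image: hydrogens are wrapped into the box)
  dh <- fr$water_h[seq(1, 999, 2), ] - fr$water_o
  dh <- dh - fr$box * round(dh / fr$box)
  expect_equal(sqrt(rowSums(dh^2)), rep(0.1, 500), tolerance = 1e-9)
  # zero exclusion allows arbitrary approach; dry frame is legal
  fr0 <- solvate(h, 5, 2000, depletion_radius = 0, clash_radius = 0,
                 seed = 4)
  expect_lt(min(helicoil:::min_image_dist(fr0$water_o, backbone_com(fr0),
                                          fr0$box)), 0.4)
  expect_equal(nrow(solvate(h, 5, 0, seed = 1)$water_o), 0)
  expect_error(solvate(h, 1.2, 100, seed = 1), "box")
})

test_that("trajectory kinds have the promised RMSD structure", {
  m <- build_topology(10, "triazole", TRUE)
  th <- generate_trajectory(m, "stable_helix", 30, 0.1, seed = 5)
  r <- rmsd_time_trace(th, n_exclude = 0)$rmsd
  expect_true(all(r <= 0.08))
  tf <- generate_trajectory(m, "folding", 60, 1.0, seed = 5)
  rf <- rmsd_time_trace(tf, n_exclude = 0)$rmsd
  expect_lt(mean(tail(rf, 6)), mean(head(rf, 6)))
  t1 <- generate_trajectory(m, "stable_coil", 1, 0.1, seed = 5)
  expect_length(t1$frames, 1)
  expect_error(generate_trajectory(m, "melting", 5, 0.1, 1), "arg")
})

test_that("synthetic SANS curves are seeded and noiseless at zero noise", {
  p <- sans_model_params(sld_particle = 4, power_amp = 1e-6,
                         background = 0.002)
  c0 <- simulate_sans_curve(p, relative_noise = 0)
  expect_equal(c0$I, composite_intensity(c0$q, p), tolerance = 1e-12)
  expect_equal(range(c0$q), c(0.0057, 0.32), tolerance = 1e-9)
  c1 <- simulate_sans_curve(p, relative_noise = 0.02, seed = 9)
  expect_identical(c1$I, simulate_sans_curve(p, relative_noise = 0.02,
                                             seed = 9)$I)
  expect_error(simulate_sans_curve(p, q = c(0.2, 0.1)), "increasing")
})

test_that("contrast series construction respects the swelling rule", {
  ser <- simulate_contrast_series(preset = "pH2", relative_noise = 0)
  expect_length(ser$curves, 3)
  qs <- lapply(ser$curves, `[[`, "q")
  expect_identical(qs[[1]], qs[[2]])
  expect_identical(qs[[1]], qs[[3]])
  # matched-out limit: phi_water = 1 gives a flat curve at background
  # plus power law only
  ser1 <- simulate_contrast_series(geometry = list(radius = 13, length = 75),
                                   phi_water = 1, sld_dry = 1.8,
                                   relative_noise = 0, power_amp = 0)
  for (cu in ser1$curves) {
    expect_lt(max(cu$I) - min(cu$I), 1e-10)
  }
  # dry particle: particle SLD constant across contrasts
  ser0 <- simulate_contrast_series(phi_water = 0, sld_dry = 1.8,
                                   relative_noise = 0)
  expect_equal(ser0$truth$phi_water, 0)
  expect_error(simulate_contrast_series(d2o_fractions = numeric(0)),
               "empty contrast")
})

test_that("titration generator follows Henderson-Hasselbalch", {
  tc <- simulate_titration(4.1, pH_grid = c(2, 4.1, 7), noise_sd = 0)
  expect_equal(tc$fraction[2], 0.5)
  expect_equal(tc$fraction[3], 1 / (1 + 10^2.9), tolerance = 1e-12)
  expect_true(all(diff(simulate_titration(4.1)$fraction) < 0))
  noisy <- simulate_titration(4.1, noise_sd = 0.05, seed = 2)
  expect_true(all(noisy$fraction >= 0 & noisy$fraction <= 1))
  expect_error(simulate_titration(4.1, pH_grid = numeric(0)), "empty")
})
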