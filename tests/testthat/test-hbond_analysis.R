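test_that("ideal n-mer helix has exactly n - 4 backbone bonds (oracle)", {
  for (n in c(5, 8, 10, 14)) {
    m <- build_topology(n, "triazole", FALSE)
    h <- generate_ideal_helix(n, model = m)
    b <- detect_hbonds(h, m)
    bb <- b[b$class == "BB", ]
    expect_equal(nrow(bb), n - 4, info = paste("n =", n))
    oracle <- brute_force_bb_hbonds(h)
    expect_equal(nrow(oracle), n - 4)
    # identical i -> i+4 registry in both routes
    expect_setequal(paste(m$atoms$residue[bb$donor],
                          m$atoms$residue[bb$acceptor]),
                    paste(oracle[, "donor_res"], oracle[, "acceptor_res"]))
    expect_true(all(oracle[, "donor_res"] - oracle[, "acceptor_res"] == 4))
  }
})

test_that("distance and angle cutoffs gate detection", {
  m <- build_topology(10, "triazole", FALSE)
  h <- generate_ideal_helix(10, model = m)
  # tight distance cutoff removes all bonds (N...O is ~0.31 nm here)
  expect_equal(nrow(detect_hbonds(h, m, dist_cutoff = 0.25)), 0)
  expect_equal(nrow(detect_hbonds(h, m, angle_cutoff = 1)), 0)
  expect_error(detect_hbonds(h, m, dist_cutoff = -1), "cutoffs")
  # frame/model mismatch rejected
  m8 <- build_topology(8, "triazole", FALSE)
  expect_error(detect_hbonds(h, m8), "mismatch")
})

test_that("triazolium side-chains never accept", {
  mp <- build_topology(10, "triazole", TRUE)
  h <- generate_ideal_helix(10, model = mp)
  fr <- solvate(h, 6, 1500, depletion_radius = 0, seed = 8)
  b <- detect_hbonds(fr, mp)
  n3 <- mp$atoms$atom_id[mp$atoms$name == "N3"]
  expect_equal(sum(b$acceptor %in% n3), 0)
  # and in vacuum, with no waters, BW is zero
  bv <- detect_hbonds(h, mp)
  expect_equal(sum(bv$class == "BW"), 0)
})

test_that("classification partition is exhaustive and disjoint", {
  m <- build_topology(10, "triazole", FALSE)
  h <- generate_ideal_helix(10, model = m)
  fr <- solvate(h, 5, 800, depletion_radius = 0, seed = 11)
  b <- detect_hbonds(fr, m, include = "all")
  expect_true(all(b$class %in% c("BB", "BW", "BS", "other")))
  expect_equal(sum(b$class == "BB") + sum(b$class == "BW") +
                 sum(b$class == "BS") + sum(b$class == "other"), nrow(b))
  # one bond per donor hydrogen
  expect_false(anyDuplicated(b$hydrogen) > 0)
  # every bond inside the cutoffs, donor != acceptor
  expect_true(all(b$distance <= 0.35 & b$angle <= 30))
  expect_true(all(b$donor != b$acceptor))
  # classify_hbond agrees with the stored labels
  relab <- vapply(seq_len(nrow(b)), function(i)
    classify_hbond(b[i, ], m), character(1))
  expect_identical(relab, b$class)
  expect_error(classify_hbond(list(donor = -1, acceptor = 2), m),
               "unresolvable")
})

test_that("per-residue stats normalise and exclude termini correctly", {
  m <- build_topology(10, "triazole", FALSE)
  traj <- generate_trajectory(m, "stable_helix", 5, 0.1, seed = 3,
                              amplitude = 0)
  st <- per_residue_hbond_stats(traj, n_exclude = 0)
  expect_equal(unname(st$mean["BB"]), 0.6)   # 6 bonds / 10 residues
  expect_equal(unname(st$sd["BB"]), 0)       # identical frames
  expect_equal(unname(st$mean["BW"]), 0)
  # excluding 2 residues per end drops the denominator to 6 and removes
  # bonds touching residues 1, 2, 9, 10
  st2 <- per_residue_hbond_stats(traj, n_exclude = 2)
  expect_equal(st2$n_residues_included, 6)
  # surviving bonds: donors 5..8 -> acceptors 3..6 intersected with
  # included residues 3..8: donors 7,8 excluded? no: donors 5..10 ->
  # acceptors 1..6; both ends included only for pairs (7->3), (8->4)
  expect_equal(unname(st2$mean["BB"]), 2 / 6)
  expect_error(per_residue_hbond_stats(traj, n_exclude = 5), "no residues")
})

test_that("dense solvation hydrates a coil's backbone", {
  m <- build_topology(10, "triazole", FALSE)
  co <- generate_random_coil(10, 4, model = m)
  fr <- solvate(co, 4, 2100, depletion_radius = 0, seed = 5)
  traj <- structure(list(frames = list(fr), time_step = 0.1, model = m,
                         kind = "adhoc"), class = "Trajectory")
  st <- per_residue_hbond_stats(traj)
  # most backbone amides find water partners at liquid-like density
  expect_gt(unname(st$mean["BW"]), 0.9)
})

test_that("dangling-group counts match the helical register", {
  m <- build_topology(10, "triazole", FALSE)
  expect_equal(count_dangling_backbone_groups(generate_ideal_helix(10, model = m), m),
               c(free_NH = 4, free_CO = 4))
  m5 <- build_topology(5, "triazole", FALSE)
  expect_equal(count_dangling_backbone_groups(generate_ideal_helix(5, model = m5), m5),
               c(free_NH = 4, free_CO = 4))   # single 1 -> 5 bond
  # fully extended chain: every group free
  line <- cbind(seq(0, by = 0.38, length.out = 10), 0, 0)
  pad <- rbind(2 * line[1, ] - line[2, ], line, 2 * line[10, ] - line[9, ])
  ext <- helicoil:::new_conformation(helicoil:::place_atoms(m, pad), m)
  expect_equal(count_dangling_backbone_groups(ext, m),
               c(free_NH = 10, free_CO = 10))
})
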