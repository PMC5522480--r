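# Synthetic conformations, solvated frames and trajectories.
#
# Coordinates are in nm throughout. A Conformation pairs an atom coordinate
# matrix (rows in PeptideModel atom order) with its model. Backbone N/H/C/O
# atoms are placed from the C-alpha trace using fixed offsets in a local
# discrete-Frenet frame; the offsets were derived once from an ideal
# alpha-helix built with canonical internal coordinates (phi = -57,
# psi = -47 deg, Engh-Huber bond geometry), so an ideal C-alpha helix yields
# the canonical alpha-helical backbone, including the i -> i+4 N-H...O=C
# geometry.

# local-frame offsets (nm) relative to C-alpha: components along
# (t = chain tangent, n = inward normal, b = t x n)
BACKBONE_OFFSETS <- list(
  N = c(-0.1097818,  0.0890748, -0.0356548),
  H = c(-0.1492704,  0.0830653, -0.1273311),
  C = c( 0.1225294,  0.0787976,  0.0450969),
  O = c( 0.1834742,  0.0474881,  0.1473665)
)

CA_STEP <- 0.38  # virtual C-alpha bond length, nm

# evaluate an expression with a temporary RNG seed, restoring global state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

new_conformation <- function(xyz, model) {
  stopifnot(nrow(xyz) == nrow(model$atoms))
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  structure(list(xyz = xyz, model = model), class = "Conformation")
}

#' Extract the C-alpha coordinate trace of a conformation
#' @param conf a `Conformation`.
#' @return numeric matrix (n_residues x 3), nm.
#' @export
calpha <- function(conf) {
  stopifnot(inherits(conf, "Conformation"))
  conf$xyz[conf$model$atoms$name == "CA", , drop = FALSE]
}

unit <- function(v) v / sqrt(sum(v^2))

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# discrete frame at interior point i of a padded trace (rows 0..n+1 stored
# as 1..n+2); returns 3x3 matrix with rows t, n, b
local_frame <- function(ca_pad, i) {
  tt <- unit(ca_pad[i + 2, ] - ca_pad[i, ])
  v <- ca_pad[i, ] + ca_pad[i + 2, ] - 2 * ca_pad[i + 1, ]
  nn <- v - sum(v * tt) * tt
  ln <- sqrt(sum(nn^2))
  if (ln < 1e-12) {  # locally straight: pick any perpendicular
    nn <- cross3(tt, if (abs(tt[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0))
    nn <- unit(nn)
  } else nn <- nn / ln
  rbind(tt, nn, cross3(tt, nn))
}

# side-chain atom offsets (nm) along (u = outward normal, b) for each atom
# name; coarse pseudo-geometry, bonded neighbours within 0.25 nm
sidechain_offset <- function(name) {
  switch(name,
    CB = c(u = 0.153, b = 0.00),
    N3 = c(u = 0.360, b = 0.065),
    H3 = c(u = 0.461, b = 0.065),
    C5 = c(u = 0.360, b = -0.065),
    H5 = c(u = 0.465, b = -0.065),
    OS = c(u = 0.360, b = -0.065),
    NS = c(u = 0.360, b = 0.065),
    HS = c(u = 0.460, b = 0.065),
    NT = c(u = 0.600, b = 0.00),
    stop("no side-chain geometry for atom ", name))
}

# build the full-atom coordinate matrix from a padded C-alpha trace
place_atoms <- function(model, ca_pad) {
  n <- model$n_residues
  atoms <- model$atoms
  xyz <- matrix(NA_real_, nrow(atoms), 3)
  for (i in seq_len(n)) {
    F <- local_frame(ca_pad, i)          # rows t, n, b
    ca_i <- ca_pad[i + 1, ]
    u <- -F[2, ]                          # outward (away from curvature centre)
    rows <- which(atoms$residue == i)
    for (k in rows) {
      nm <- atoms$name[k]
      if (nm == "CA") xyz[k, ] <- ca_i
      else if (nm %in% names(BACKBONE_OFFSETS)) {
        o <- BACKBONE_OFFSETS[[nm]]
        xyz[k, ] <- ca_i + o[1] * F[1, ] + o[2] * F[2, ] + o[3] * F[3, ]
      } else {
        o <- sidechain_offset(nm)
        xyz[k, ] <- ca_i + o[["u"]] * u + o[["b"]] * F[3, ]
      }
    }
  }
  xyz
}

# parametric right-handed helix C-alpha trace, indices idx (0-based allowed)
helix_trace <- function(idx, radius, twist, rise) {
  th <- idx * twist * pi / 180
  cbind(radius * cos(th), radius * sin(th), idx * rise)
}

#' Generate an ideal alpha-helical conformation
#'
#' C-alpha atoms are placed exactly on a cylindrical helix of the given
#' radius, per-residue twist and rise; backbone N/H/C/O (and coarse
#' side-chain sites) are placed at canonical alpha-helical geometry relative
#' to the trace. Defaults are the ideal alpha-helix: radius 0.23 nm, twist
#' 100 deg (3.6 residues/turn), rise 0.15 nm.
#'
#' @param n_residues chain length (>= 2).
#' @param radius helix radius, nm (> 0).
#' @param twist per-residue rotation, degrees, in (0, 180).
#' @param rise per-residue axial translation, nm (> 0).
#' @param model optional `PeptideModel` (default: unprotonated triazole
#'   `n_residues`-mer).
#' @return a `Conformation`.
#' @examples
#' h <- generate_ideal_helix(10)
#' range(sqrt(rowSums(calpha(h)[, 1:2]^2)))  # all exactly 0.23
#' @export
generate_ideal_helix <- function(n_residues, radius = 0.23, twist = 100,
                                 rise = 0.15, model = NULL) {
  if (n_residues < 2) stop("n_residues must be >= 2")
  if (radius <= 0 || rise <= 0 || twist <= 0 || twist >= 180)
    stop("non-physical helix parameters")
  if (is.null(model)) model <- build_topology(n_residues, "triazole", FALSE)
  stopifnot(model$n_residues == n_residues)
  ca_pad <- helix_trace(seq(-1, n_residues), radius, twist, rise)
  new_conformation(place_atoms(model, ca_pad), model)
}

#' Generate a random-coil conformation
#'
#' The C-alpha trace is a fixed-step (0.38 nm) self-avoiding random walk in
#' which no two non-bonded C-alpha atoms approach closer than `min_dist`.
#' Backbone and side-chain atoms are placed in the local trace frame as for
#' the helix generator. Reproducible for a given seed.
#'
#' @param n_residues chain length (>= 2).
#' @param seed integer RNG seed.
#' @param min_dist self-avoidance distance, nm.
#' @param model optional `PeptideModel`.
#' @param max_tries per-step direction attempts before restarting the walk.
#' @param max_restarts whole-walk attempts before giving up with an error.
#' @return a `Conformation`.
#' @export
generate_random_coil <- function(n_residues, seed, min_dist = 0.4,
                                 model = NULL, max_tries = 200,
                                 max_restarts = 50) {
  if (n_residues < 2) stop("n_residues must be >= 2")
  if (is.null(model)) model <- build_topology(n_residues, "triazole", FALSE)
  stopifnot(model$n_residues == n_residues)
  ca <- with_seed(seed, {
    for (attempt in seq_len(max_restarts)) {
      pts <- matrix(NA_real_, n_residues, 3)
      pts[1, ] <- 0
      dir <- unit(rnorm(3))
      pts[2, ] <- pts[1, ] + CA_STEP * dir
      ok <- TRUE
      for (i in seq_len(n_residues - 2) + 2) {
        placed <- FALSE
        for (t in seq_len(max_tries)) {
          # bias towards persistence to keep acceptance high
          cand_dir <- unit(dir + 0.8 * rnorm(3))
          cand <- pts[i - 1, ] + CA_STEP * cand_dir
          d2 <- rowSums((pts[seq_len(i - 2), , drop = FALSE] -
                           matrix(cand, i - 2, 3, byrow = TRUE))^2)
          if (all(d2 >= min_dist^2)) {
            pts[i, ] <- cand; dir <- cand_dir; placed <- TRUE; break
          }
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (ok) break
    }
    if (!ok) stop("self-avoiding walk failed to place after ",
                  max_restarts, " restarts")
    pts
  })
  ca_pad <- rbind(2 * ca[1, ] - ca[2, ], ca,
                  2 * ca[n_residues, ] - ca[n_residues - 1, ])
  new_conformation(place_atoms(model, ca_pad), model)
}

#' Perturb a conformation with isotropic Gaussian noise
#'
#' Thermal-fluctuation stand-in: every atom is displaced independently with
#' an isotropic Gaussian of the given standard deviation per coordinate...
#' amplitude 0 returns the input exactly (bit-identical).
#'
#' @param conf a `Conformation`.
#' @param amplitude per-atom displacement s.d., nm (>= 0).
#' @param seed integer RNG seed.
#' @return a perturbed `Conformation`.
#' @export
perturb_conformation <- function(conf, amplitude, seed) {
  stopifnot(inherits(conf, "Conformation"))
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (amplitude == 0) return(conf)
  xyz <- with_seed(seed, {
    conf$xyz + matrix(rnorm(length(conf$xyz), sd = amplitude),
                      nrow(conf$xyz), 3)
  })
  new_conformation(xyz, conf$model)
}

#' Solvate a conformation in a cubic periodic box
#'
#' Water oxygens are placed uniformly at random in the box, excluding a
#' planted depletion sphere of radius `depletion_radius` about the backbone
#' centre of mass and excluding positions within 0.25 nm of any peptide
#' atom (minimum-image convention). Each water carries two hydrogens at
#' 0.1 nm from the oxygen with a 104.5 deg H-O-H angle and random
#' orientation. The peptide is re-centred at the box centre.
#'
#' @param conf a `Conformation`.
#' @param box_edge cubic box edge, nm.
#' @param n_waters number of waters (>= 0).
#' @param depletion_radius planted exclusion radius about the backbone COM,
#'   nm (>= 0).
#' @param clash_radius minimum water-oxygen distance to any peptide atom,
#'   nm (0 disables the steric exclusion, leaving an ideal-gas water
#'   field).
#' @param orient `"shell"` (default) points one O-H of every water within
#'   0.45 nm of the peptide at its nearest peptide atom, mimicking
#'   hydration-shell ordering; `"random"` orients all waters uniformly.
#' @param seed integer RNG seed.
#' @param time time stamp, ns.
#' @return a `Frame`: list with `conf`, `water_o` (n x 3), `water_h`
#'   (2n x 3), `box` (nm), `time` (ns).
#' @export
solvate <- function(conf, box_edge, n_waters, depletion_radius = 0,
                    clash_radius = 0.25, orient = c("shell", "random"),
                    seed = 1, time = 0) {
  orient <- match.arg(orient)
  stopifnot(inherits(conf, "Conformation"))
  if (n_waters < 0) stop("n_waters must be >= 0")
  if (depletion_radius < 0) stop("depletion_radius must be >= 0")
  ext <- apply(conf$xyz, 2, function(v) diff(range(v)))
  if (any(ext >= box_edge))
    stop("box_edge smaller than peptide extent (", round(max(ext), 2), " nm)")
  centre <- rep(box_edge / 2, 3)
  shift <- centre - colMeans(conf$xyz)
  xyz <- sweep(conf$xyz, 2, shift, `+`)
  conf <- new_conformation(xyz, conf$model)
  frame <- structure(list(conf = conf, water_o = matrix(numeric(0), 0, 3),
                          water_h = matrix(numeric(0), 0, 3),
                          box = box_edge, time = time), class = "Frame")
  if (n_waters == 0) return(frame)

  com <- backbone_com(frame)
  # acceptance volume sanity check
  v_excl <- 4 / 3 * pi * depletion_radius^3 +
    nrow(xyz) * 4 / 3 * pi * clash_radius^3
  v_free <- box_edge^3 - v_excl
  # each water effectively occupies no volume here (ideal-gas placement),
  # but refuse clearly impossible requests
  if (v_free <= 0.05 * box_edge^3)
    stop("box too small to host ", n_waters, " waters")

  ow <- with_seed(seed, {
    acc <- matrix(NA_real_, 0, 3)
    guard <- 0L
    while (nrow(acc) < n_waters) {
      guard <- guard + 1L
      if (guard > 1000L) stop("box too small to host ", n_waters, " waters")
      m <- max(2L * (n_waters - nrow(acc)), 64L)
      cand <- matrix(runif(3 * m, 0, box_edge), m, 3)
      d_com <- min_image_dist(cand, com, box_edge)
      keep <- d_com >= depletion_radius
      if (any(keep)) {
        cnd <- cand[keep, , drop = FALSE]
        if (clash_radius > 0) {
          dmin <- min_dist_to_set(cnd, xyz, box_edge)
          cnd <- cnd[dmin >= clash_radius, , drop = FALSE]
        }
        if (nrow(cnd) > 0) acc <- rbind(acc, cnd)
      }
    }
    acc[seq_len(n_waters), , drop = FALSE]
  })
  # first-shell waters orient one O-H towards their nearest peptide atom
  # (hydration-shell ordering the H-bond analysis assumes); bulk waters
  # are oriented at random
  near_target <- matrix(NA_real_, n_waters, 3)
  if (orient == "shell" && n_waters > 0) {
    for (i in seq_len(n_waters)) {
      d <- min_image_dist(xyz, ow[i, ], box_edge)
      j <- which.min(d)
      if (d[j] <= 0.45) {
        v <- xyz[j, ] - ow[i, ]
        near_target[i, ] <- v - box_edge * round(v / box_edge)
      }
    }
  }
  hw <- with_seed(if (is.null(seed)) NULL else seed + 1L, {
    out <- matrix(NA_real_, 2 * n_waters, 3)
    half <- 104.5 / 2 * pi / 180
    for (i in seq_len(n_waters)) {
      a1 <- if (!is.na(near_target[i, 1])) unit(near_target[i, ])
      else unit(rnorm(3))
      perp <- unit(cross3(a1, rnorm(3)))
      # one O-H along a1 (at the target), the other at the H-O-H angle
      h1 <- a1
      h2 <- cos(2 * half) * a1 + sin(2 * half) * perp
      out[2 * i - 1, ] <- ow[i, ] + 0.1 * h1
      out[2 * i, ] <- ow[i, ] + 0.1 * h2
    }
    out
  })
  frame$water_o <- ow
  frame$water_h <- hw %% box_edge
  frame
}

# minimum-image distance from each row of `pts` to single point `p`
min_image_dist <- function(pts, p, box) {
  d <- sweep(pts, 2, p)
  d <- d - box * round(d / box)
  sqrt(rowSums(d^2))
}

# minimum over `set` rows of min-image distance, for each row of `pts`
min_dist_to_set <- function(pts, set, box) {
  out <- rep(Inf, nrow(pts))
  for (j in seq_len(nrow(set))) {
    d <- min_image_dist(pts, set[j, ], box)
    out <- pmin(out, d)
  }
  out
}

#' Generate a synthetic trajectory
#'
#' `stable_helix` and `stable_coil` produce thermally perturbed copies of a
#' single reference conformation (ideal helix / self-avoiding coil).
#' `folding` interpolates the C-alpha trace from the coil to the helix,
#' with the transition starting at `switch_frac` of the frames and
#' completing over `ramp_frac`, so the expected helix RMSD decreases
#' monotonically -- a geometric stand-in for a folding run, not physics.
#'
#' @param model a `PeptideModel`.
#' @param kind one of `"stable_coil"`, `"stable_helix"`, `"folding"`.
#' @param n_frames number of frames (>= 1).
#' @param time_step frame spacing, ns.
#' @param seed integer RNG seed.
#' @param amplitude per-atom thermal noise s.d., nm.
#' @param n_waters waters per frame (0 = dry trajectory).
#' @param box_edge cubic box edge used when solvating, nm.
#' @param depletion_radius planted water-exclusion radius about the backbone
#'   COM; default 0.4 nm for `stable_helix` (compact packed backbone),
#'   0 otherwise.
#' @param switch_frac,ramp_frac folding-transition timing as fractions of
#'   the trajectory.
#' @return a `Trajectory`: list with `frames` (list of `Frame`),
#'   `time_step`, `model`, `kind`.
#' @export
generate_trajectory <- function(model, kind = c("stable_coil", "stable_helix",
                                                "folding"),
                                n_frames, time_step = 0.1, seed = 1,
                                amplitude = 0.02, n_waters = 0,
                                box_edge = 6,
                                depletion_radius = NULL,
                                switch_frac = 0.4, ramp_frac = 0.3) {
  kind <- match.arg(kind)
  if (n_frames < 1) stop("n_frames must be >= 1")
  n <- model$n_residues
  if (is.null(depletion_radius))
    depletion_radius <- if (kind == "stable_helix") 0.4 else 0
  helix <- generate_ideal_helix(n, model = model)
  coil <- if (kind != "stable_helix") generate_random_coil(n, seed, model = model)
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    base <- switch(kind,
      stable_helix = helix,
      stable_coil = coil,
      folding = {
        lam <- min(1, max(0, ((f - 1) / max(1, n_frames - 1) - switch_frac) /
                            ramp_frac))
        ca_mix <- (1 - lam) * calpha(coil) + lam * calpha(helix)
        ca_pad <- rbind(2 * ca_mix[1, ] - ca_mix[2, ], ca_mix,
                        2 * ca_mix[n, ] - ca_mix[n - 1, ])
        new_conformation(place_atoms(model, ca_pad), model)
      })
    conf <- perturb_conformation(base, amplitude, seed + 1000L + f)
    frames[[f]] <- if (n_waters > 0)
      solvate(conf, box_edge, n_waters, depletion_radius,
              seed = seed + 5000L + f, time = (f - 1) * time_step)
    else {
      fr <- structure(list(conf = conf, water_o = matrix(numeric(0), 0, 3),
                           water_h = matrix(numeric(0), 0, 3),
                           box = box_edge, time = (f - 1) * time_step),
                      class = "Frame")
      fr
    }
  }
  structure(list(frames = frames, time_step = time_step, model = model,
                 kind = kind), class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames (%s), dt = %g ns, %d-mer, %d waters/frame\n",
              length(x$frames), x$kind, x$time_step, x$model$n_residues,
              nrow(x$frames[[1]]$water_o)))
  invisible(x)
}
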