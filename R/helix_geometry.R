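# Helix-parameter fitting for C-alpha traces.
#
# Axis estimation: second differences of an ideal helical trace are purely
# radial, so the null direction of their SVD is the axis; the axis point and
# radius then follow from an algebraic (Kasa) circle fit of the projected
# points, both exact on noiseless input. A Nelder-Mead refinement of
# (axis direction, axis point) minimising the variance of perpendicular
# distances adds robustness to noise.

coerce_calpha <- function(x) {
  if (inherits(x, "Conformation")) calpha(x)
  else if (is.matrix(x) && ncol(x) == 3) x
  else stop("expected a Conformation or an n x 3 coordinate matrix")
}

kasa_circle <- function(xy) {
  A <- cbind(2 * xy, 1)
  b <- rowSums(xy^2)
  sol <- qr.solve(A, b)
  c(cx = sol[[1]], cy = sol[[2]],
    r = sqrt(max(sol[[3]] + sol[[1]]^2 + sol[[2]]^2, 0)))
}

# perpendicular distances of points to the line (p0, dir)
axis_dist <- function(pts, p0, dir) {
  d <- sweep(pts, 2, p0)
  along <- drop(d %*% dir)
  sqrt(pmax(rowSums(d^2) - along^2, 0))
}

#' Fit helical parameters to a C-alpha trace
#'
#' Estimates the helix axis, radius, mean per-residue twist and rise of an
#' ordered C-alpha trace. `n_exclude` residues are dropped from each end
#' before fitting (chain ends deviate from the ideal geometry; the
#' trajectory analyses use 2 by default, exact synthetic helices 0).
#'
#' @param x a `Conformation` or an ordered n x 3 C-alpha matrix (nm).
#' @param n_exclude residues excluded at each end (>= 0); at least 4 atoms
#'   must remain.
#' @param refine logical; run the variance-minimising axis refinement
#'   (exact inputs are already exact without it).
#' @return a `HelixFit`: list with `axis_point`, `axis_dir` (unit vector),
#'   `radius` (nm), `twist` (deg, magnitude in (0, 180]), `rise` (nm),
#'   `handedness` (+1 right-handed, -1 left-handed), `rmsd_helix` (nm, vs
#'   the default ideal helix), `n_excluded_termini`, `degenerate` flag.
#' @examples
#' f <- fit_helix(generate_ideal_helix(10), n_exclude = 0)
#' c(f$radius, f$twist, f$rise)   # 0.23, 100, 0.15
#' @export
fit_helix <- function(x, n_exclude = 2, refine = TRUE) {
  ca_all <- coerce_calpha(x)
  n_all <- nrow(ca_all)
  if (n_exclude < 0) stop("n_exclude must be >= 0")
  keep <- seq_len(n_all)
  if (n_exclude > 0) keep <- keep[-c(seq_len(n_exclude),
                                     n_all - seq_len(n_exclude) + 1)]
  ca <- ca_all[keep, , drop = FALSE]
  n <- nrow(ca)
  if (n < 4) stop("need at least 4 C-alpha atoms after exclusion")

  d2 <- ca[1:(n - 2), , drop = FALSE] - 2 * ca[2:(n - 1), , drop = FALSE] +
    ca[3:n, , drop = FALSE]
  if (max(abs(d2)) < 1e-9) {
    # collinear trace: no curvature, flag degenerate fit
    fit <- structure(list(axis_point = colMeans(ca),
                          axis_dir = unit(ca[n, ] - ca[1, ]),
                          radius = 0, twist = NA_real_,
                          rise = mean(sqrt(rowSums(diff(ca)^2))),
                          handedness = NA_integer_, rmsd_helix = NA_real_,
                          n_excluded_termini = n_exclude,
                          degenerate = TRUE), class = "HelixFit")
    return(fit)
  }
  sv <- svd(d2)
  axis <- sv$v[, 3]
  ete <- ca[n, ] - ca[1, ]
  if (sum(axis * ete) < 0) axis <- -axis

  basis <- function(dir) {
    e1 <- unit(cross3(dir, if (abs(dir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)))
    rbind(e1, cross3(dir, e1))
  }
  centre_in_plane <- function(dir) {
    B <- basis(dir)
    xy <- ca %*% t(B)
    k <- kasa_circle(xy)
    list(B = B, centre2d = k[1:2], radius = k[[3]],
         p0 = drop(k[1] * B[1, ] + k[2] * B[2, ]))
  }
  est <- centre_in_plane(axis)

  if (refine) {
    # parameterize axis as small rotations of the SVD estimate
    obj <- function(par) {
      dir <- unit(axis + par[1] * est$B[1, ] + par[2] * est$B[2, ])
      cc <- centre_in_plane(dir)
      d <- axis_dist(ca, cc$p0, dir)
      stats::var(d)
    }
    opt <- stats::optim(c(0, 0), obj, method = "Nelder-Mead",
                        control = list(maxit = 300, reltol = 1e-14))
    axis <- unit(axis + opt$par[1] * est$B[1, ] + opt$par[2] * est$B[2, ])
    if (sum(axis * ete) < 0) axis <- -axis
    est <- centre_in_plane(axis)
  }

  d <- axis_dist(ca, est$p0, axis)
  radius <- mean(d)
  z <- drop(ca %*% axis)
  rise <- mean(abs(diff(z)))
  xy <- sweep(ca %*% t(est$B), 2, est$centre2d)
  ang <- atan2(xy[, 2], xy[, 1])
  dtw <- diff(ang)
  dtw <- (dtw + pi) %% (2 * pi) - pi     # wrap to (-pi, pi]
  # rotation sign about `axis`: with B = (e1, e2 = axis x e1) the frame
  # (e1, e2, axis) is right-handed, so positive dtw = right-handed twist
  mean_signed <- mean(dtw) * 180 / pi
  handedness <- if (mean_signed >= 0) 1L else -1L
  twist <- abs(mean_signed)
  if (twist == 0) twist <- 180  # report in (0, 180]

  rmsd <- tryCatch(rmsd_to_ideal_helix(ca_all, n_exclude = n_exclude),
                   error = function(e) NA_real_)
  structure(list(axis_point = est$p0, axis_dir = axis, radius = radius,
                 twist = twist, rise = rise, handedness = handedness,
                 rmsd_helix = rmsd, n_excluded_termini = n_exclude,
                 degenerate = FALSE),
            class = "HelixFit")
}

#' @export
print.HelixFit <- function(x, ...) {
  if (x$degenerate) cat("HelixFit: degenerate (collinear trace), radius 0\n")
  else cat(sprintf(
    "HelixFit: radius %.4f nm, twist %.2f deg (%s-handed), rise %.4f nm, RMSD_helix %.4f nm\n",
    x$radius, x$twist, if (x$handedness > 0) "right" else "left", x$rise,
    x$rmsd_helix))
  invisible(x)
}

# RMSD after optimal rigid superposition (Kabsch: SVD of the covariance,
# with the determinant correction against improper rotations)
superposed_rmsd <- function(a, b) {
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  s <- svd(t(ac) %*% bc)
  d <- sign(det(s$u %*% t(s$v)))
  Q <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sqrt(mean(rowSums((ac %*% Q - bc)^2)))
}

#' RMSD of a C-alpha trace from an ideal alpha-helix
#'
#' Builds an ideal helix of matching residue count, optimally superposes it
#' (least-squares rigid rotation + translation over the included atoms) and
#' returns the C-alpha RMSD. The ideal reference defaults to radius
#' 0.23 nm, twist 100 deg, rise 0.15 nm.
#'
#' @param x a `Conformation` or n x 3 C-alpha matrix (nm).
#' @param ideal_radius,ideal_twist,ideal_rise ideal-helix parameters.
#' @param n_exclude residues excluded at each end before superposition.
#' @return RMSD in nm.
#' @export
rmsd_to_ideal_helix <- function(x, ideal_radius = 0.23, ideal_twist = 100,
                                ideal_rise = 0.15, n_exclude = 0) {
  ca <- coerce_calpha(x)
  n_all <- nrow(ca)
  keep <- seq_len(n_all)
  if (n_exclude > 0) keep <- keep[-c(seq_len(n_exclude),
                                     n_all - seq_len(n_exclude) + 1)]
  ca <- ca[keep, , drop = FALSE]
  if (nrow(ca) < 3) stop("need at least 3 C-alpha atoms after exclusion")
  ideal <- helix_trace(seq_len(nrow(ca)) - 1, ideal_radius, ideal_twist,
                       ideal_rise)
  superposed_rmsd(ca, ideal)
}

#' Helix-RMSD time trace of a trajectory
#'
#' One RMSD value per frame, in frame order; frames whose fit fails yield
#' `NA` with a warning rather than aborting the trace.
#'
#' @param traj a `Trajectory`.
#' @param ideal_radius,ideal_twist,ideal_rise ideal-helix reference.
#' @param n_exclude residues excluded at each end.
#' @return data frame with columns `time` (ns) and `rmsd` (nm).
#' @export
rmsd_time_trace <- function(traj, ideal_radius = 0.23, ideal_twist = 100,
                            ideal_rise = 0.15, n_exclude = 2) {
  stopifnot(inherits(traj, "Trajectory"))
  if (length(traj$frames) < 1) stop("trajectory is empty")
  out <- vapply(traj$frames, function(fr) {
    tryCatch(rmsd_to_ideal_helix(fr$conf, ideal_radius, ideal_twist,
                                 ideal_rise, n_exclude),
             error = function(e) { warning(conditionMessage(e)); NA_real_ })
  }, numeric(1))
  data.frame(time = vapply(traj$frames, `[[`, numeric(1), "time"),
             rmsd = out)
}
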