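# Backbone-COM to water-oxygen radial distribution function with
# block-averaged errors and depletion-zone detection.
#
# Distances use the minimum-image convention in the cubic box. Each bin is
# normalised by its exact shell volume times the mean instantaneous water
# number density times the frame count, so uniformly random waters give
# g = 1.

#' Mass-weighted backbone centre of mass
#'
#' @param frame a `Frame` or `Conformation`.
#' @param model the `PeptideModel` (defaults to the conformation's model).
#' @return 3-vector, nm.
#' @export
backbone_com <- function(frame, model = NULL) {
  conf <- if (inherits(frame, "Frame")) frame$conf else frame
  stopifnot(inherits(conf, "Conformation"))
  if (is.null(model)) model <- conf$model
  bb <- model$atoms$region == "backbone"
  if (!any(bb)) stop("no backbone atoms in model")
  w <- model$atoms$mass[bb]
  drop(w %*% conf$xyz[bb, , drop = FALSE]) / sum(w)
}

rdf_histogram <- function(frames, model, breaks, box) {
  counts <- numeric(length(breaks) - 1)
  dens <- numeric(length(frames))
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    if (nrow(fr$water_o) == 0) stop("frame without waters: RDF undefined")
    com <- backbone_com(fr, model)
    d <- min_image_dist(fr$water_o, com, fr$box)
    counts <- counts + graphics::hist(d[d < max(breaks)], breaks = breaks,
                                      plot = FALSE)$counts
    dens[i] <- nrow(fr$water_o) / fr$box^3
  }
  shell <- 4 / 3 * pi * diff(breaks^3)
  expected <- length(frames) * shell * mean(dens)   # counts if g = 1
  list(g = counts / expected, counts = counts, expected = expected)
}

#' Radial distribution function g(r) between backbone COM and water oxygens
#'
#' @param traj a `Trajectory` with solvated frames.
#' @param model the `PeptideModel` (defaults to `traj$model`).
#' @param bin_width histogram bin width, nm.
#' @param r_max maximum distance, nm; defaults to (and may not exceed) half
#'   the box edge. Rounded down to a whole number of bins.
#' @return an `RDF`: data frame with `r` (bin centres), `g`, `se`
#'   (standard errors, zero unless block-averaged); attributes `bin_width`,
#'   `n_frames`, `se_valid`.
#' @export
rdf_com_water <- function(traj, model = traj$model, bin_width = 0.04,
                          r_max = NULL) {
  stopifnot(inherits(traj, "Trajectory"))
  box <- traj$frames[[1]]$box
  if (is.null(r_max)) r_max <- box / 2
  if (r_max > box / 2 + 1e-9) stop("r_max exceeds half the box edge")
  nb <- floor(r_max / bin_width + 1e-9)
  if (nb < 1) stop("r_max smaller than one bin")
  breaks <- seq(0, nb * bin_width, by = bin_width)
  h <- rdf_histogram(traj$frames, model, breaks, box)
  out <- data.frame(r = breaks[-1] - bin_width / 2, g = h$g,
                    se = rep(0, nb))
  structure(out, class = c("RDF", "data.frame"), bin_width = bin_width,
            n_frames = length(traj$frames), se_valid = FALSE,
            expected_counts = h$expected)
}

#' Block-averaged RDF with standard errors
#'
#' Frames are split into `n_blocks` contiguous blocks (the last absorbs any
#' remainder); the RDF of each block is computed independently and the
#' reported g is their per-bin mean with standard error sd / sqrt(n_blocks).
#'
#' @inheritParams rdf_com_water
#' @param n_blocks number of contiguous blocks (default 5).
#' @return an `RDF` with `se` filled in (`se_valid = TRUE` for
#'   `n_blocks > 1`; with one block errors are undefined and reported as
#'   zero with `se_valid = FALSE` and a warning).
#' @export
block_average_rdf <- function(traj, model = traj$model, n_blocks = 5,
                              bin_width = 0.04, r_max = NULL) {
  stopifnot(inherits(traj, "Trajectory"))
  nf <- length(traj$frames)
  if (nf < n_blocks) stop("fewer frames than blocks")
  box <- traj$frames[[1]]$box
  if (is.null(r_max)) r_max <- box / 2
  if (r_max > box / 2 + 1e-9) stop("r_max exceeds half the box edge")
  nb <- floor(r_max / bin_width + 1e-9)
  breaks <- seq(0, nb * bin_width, by = bin_width)
  size <- nf %/% n_blocks
  gs <- matrix(NA_real_, n_blocks, nb)
  for (b in seq_len(n_blocks)) {
    i0 <- (b - 1) * size + 1
    i1 <- if (b == n_blocks) nf else b * size
    gs[b, ] <- rdf_histogram(traj$frames[i0:i1], model, breaks, box)$g
  }
  se_valid <- n_blocks > 1
  if (!se_valid) warning("n_blocks = 1: standard errors undefined, reported as zero")
  se <- if (se_valid) apply(gs, 2, stats::sd) / sqrt(n_blocks) else rep(0, nb)
  out <- data.frame(r = breaks[-1] - bin_width / 2, g = colMeans(gs),
                    se = se)
  expected <- rdf_histogram(traj$frames[1], model, breaks, box)$expected * nf
  structure(out, class = c("RDF", "data.frame"), bin_width = bin_width,
            n_frames = nf, n_blocks = n_blocks, se_valid = se_valid,
            expected_counts = expected)
}

#' Water depletion radius from an RDF
#'
#' The largest r such that g stays below `threshold` for every bin below
#' it, scanning outward from the origin: 0 if the first bin already
#' exceeds the threshold, the outer histogram edge if no bin does.
#'
#' The innermost bins of a COM-centred RDF hold almost no volume, so at
#' finite sampling they can be empty even for uniform solvent; bins whose
#' expected uniform count falls below `min_expected` are therefore treated
#' as uninformative (consistent with no depletion) when they *lead* the
#' histogram. They still count toward the depleted run when followed by
#' well-sampled empty bins.
#'
#' @param rdf an `RDF`.
#' @param threshold dimensionless g threshold (default 0.1, a near-zero
#'   criterion for the depleted zone).
#' @param min_expected sampling floor: minimum expected uniform count for
#'   a bin to witness depletion on its own.
#' @return depletion radius, nm.
#' @export
depletion_radius <- function(rdf, threshold = 0.1, min_expected = 5) {
  stopifnot(inherits(rdf, "RDF"), nrow(rdf) > 0)
  bw <- attr(rdf, "bin_width")
  expected <- attr(rdf, "expected_counts")
  informative <- if (is.null(expected)) rep(TRUE, nrow(rdf))
  else expected >= min_expected
  below <- rdf$g < threshold
  first_inf <- which(informative)
  if (!length(first_inf)) return(0)
  i0 <- first_inf[1]
  if (!all(below[seq_len(i0)])) return(0)
  k <- which(!below)
  edge <- if (length(k)) k[1] - 1 else nrow(rdf)
  if (edge < i0) return(0)
  edge * bw
}
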