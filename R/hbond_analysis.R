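# Geometric hydrogen-bond detection and the backbone-backbone (BB),
# backbone-water (BW), backbone-side-chain (BS) partition.
#
# Criterion (conventional MD-analysis defaults, config-exposed): donor to
# acceptor heavy-atom distance <= 0.35 nm and H-donor-acceptor angle
# <= 30 deg. Donor/acceptor eligibility follows the ligand H-bonding
# pattern: a triazolium N3 is never an acceptor, an ester only accepts.
# Each donor hydrogen forms at most one bond per frame (closest acceptor
# wins, ties broken by lower atom id).

as_frame <- function(x) {
  if (inherits(x, "Frame")) x
  else if (inherits(x, "Conformation"))
    structure(list(conf = x, water_o = matrix(numeric(0), 0, 3),
                   water_h = matrix(numeric(0), 0, 3), box = NULL,
                   time = 0), class = "Frame")
  else stop("expected a Frame or Conformation")
}

# assemble the per-frame site tables: coordinates for peptide + water with
# global ids (peptide atoms first, then water O, then water H)
frame_sites <- function(frame, model) {
  atoms <- model$atoms
  if (nrow(frame$conf$xyz) != nrow(atoms))
    stop("frame/model atom-count mismatch")
  np <- nrow(atoms)
  nw <- nrow(frame$water_o)
  coords <- rbind(frame$conf$xyz, frame$water_o, frame$water_h)
  kind <- c(ifelse(atoms$region == "backbone", "backbone", "sidechain"),
            rep("water", nw), rep("water", 2 * nw))
  residue <- c(atoms$residue, rep(NA_integer_, 3 * nw))
  # donor pairs: (H id, parent heavy id)
  pep_h <- which(!is.na(atoms$h_of) & atoms$donor[atoms$h_of])
  don_h <- pep_h
  don_d <- atoms$h_of[pep_h]
  if (nw > 0) {
    wat_h <- np + nw + seq_len(2 * nw)
    wat_d <- np + rep(seq_len(nw), each = 2)
    don_h <- c(don_h, wat_h)
    don_d <- c(don_d, wat_d)
  }
  acc <- c(which(atoms$acceptor), if (nw > 0) np + seq_len(nw))
  list(coords = coords, kind = kind, residue = residue, np = np, nw = nw,
       donor_h = don_h, donor_d = don_d, acceptors = acc)
}

pair_dist <- function(a, b, box) {
  d <- a - b
  if (!is.null(box)) d <- d - box * round(d / box)
  sqrt(rowSums(d^2))
}

#' Detect hydrogen bonds in a frame
#'
#' Every (donor-H, acceptor) pair with donor-acceptor distance within
#' `dist_cutoff` and H-donor-acceptor angle within `angle_cutoff` is
#' reported, subject to the one-bond-per-hydrogen rule. Minimum-image
#' distances are used when the frame has a box.
#'
#' @param frame a `Frame` (or dry `Conformation`).
#' @param model the matching `PeptideModel`.
#' @param dist_cutoff donor-acceptor distance cutoff, nm.
#' @param angle_cutoff H-donor-acceptor angle cutoff, degrees.
#' @param include `"peptide"` (default) restricts to bonds with at least
#'   one peptide partner; `"all"` also enumerates water-water bonds
#'   (quadratic in water count -- use on small frames).
#' @return data frame of class `HBondSet`: `donor`, `hydrogen`, `acceptor`
#'   (global atom ids; waters follow the peptide atoms), `distance` (nm),
#'   `angle` (deg), `class` (`BB`, `BW`, `BS`, `other`).
#' @export
detect_hbonds <- function(frame, model, dist_cutoff = 0.35,
                          angle_cutoff = 30, include = c("peptide", "all")) {
  include <- match.arg(include)
  if (dist_cutoff <= 0 || angle_cutoff <= 0) stop("cutoffs must be > 0")
  frame <- as_frame(frame)
  s <- frame_sites(frame, model)
  box <- frame$box

  res <- list()
  for (i in seq_along(s$donor_h)) {
    hid <- s$donor_h[i]; did <- s$donor_d[i]
    if (include == "peptide" && s$kind[did] == "water") {
      acc <- s$acceptors[s$acceptors <= s$np]   # water donors: peptide acceptors only
    } else acc <- s$acceptors
    acc <- acc[acc != did & acc != hid]
    if (!length(acc)) next
    D <- matrix(s$coords[did, ], length(acc), 3, byrow = TRUE)
    dDA <- pair_dist(s$coords[acc, , drop = FALSE], D, box)
    ok <- dDA <= dist_cutoff
    if (!any(ok)) next
    acc <- acc[ok]; dDA <- dDA[ok]
    # angle at the donor heavy atom between D->H and D->A (min-image)
    vH <- s$coords[hid, ] - s$coords[did, ]
    if (!is.null(box)) vH <- vH - box * round(vH / box)
    vA <- sweep(s$coords[acc, , drop = FALSE], 2, s$coords[did, ])
    if (!is.null(box)) vA <- vA - box * round(vA / box)
    cosang <- (vA %*% vH) / (sqrt(rowSums(vA^2)) * sqrt(sum(vH^2)))
    ang <- acos(pmin(pmax(drop(cosang), -1), 1)) * 180 / pi
    ok <- ang <= angle_cutoff
    if (!any(ok)) next
    acc <- acc[ok]; dDA <- dDA[ok]; ang <- ang[ok]
    pick <- order(dDA, acc)[1]           # closest acceptor, tie: lower id
    res[[length(res) + 1]] <- data.frame(
      donor = did, hydrogen = hid, acceptor = acc[pick],
      distance = dDA[pick], angle = ang[pick])
  }
  bonds <- if (length(res)) do.call(rbind, res)
  else data.frame(donor = integer(0), hydrogen = integer(0),
                  acceptor = integer(0), distance = numeric(0),
                  angle = numeric(0))
  bonds$class <- classify_partner_kinds(s$kind[bonds$donor],
                                        s$kind[bonds$acceptor])
  class(bonds) <- c("HBondSet", "data.frame")
  attr(bonds, "n_peptide_atoms") <- s$np
  bonds
}

classify_partner_kinds <- function(kd, ka) {
  out <- rep("other", length(kd))
  out[kd == "backbone" & ka == "backbone"] <- "BB"
  out[(kd == "backbone" & ka == "water") |
        (kd == "water" & ka == "backbone")] <- "BW"
  out[(kd == "backbone" & ka == "sidechain") |
        (kd == "sidechain" & ka == "backbone")] <- "BS"
  out
}

#' Classify a hydrogen bond by its partners
#'
#' `BB` if donor and acceptor are both backbone atoms, `BW` if one is
#' backbone and the other water, `BS` if one is backbone and the other a
#' side-chain site, `other` otherwise (water-water, side-chain-water, ...).
#'
#' @param bond one row of a [detect_hbonds()] result (or a list with
#'   `donor` and `acceptor` atom ids).
#' @param model the `PeptideModel`; atom ids beyond the peptide atom table
#'   are water sites.
#' @return class label string.
#' @export
classify_hbond <- function(bond, model) {
  np <- nrow(model$atoms)
  kind_of <- function(id) {
    if (is.na(id)) stop("unresolvable atom id")
    if (id <= np) {
      if (id < 1) stop("unresolvable atom id: ", id)
      ifelse(model$atoms$region[id] == "backbone", "backbone", "sidechain")
    } else "water"
  }
  classify_partner_kinds(kind_of(bond$donor), kind_of(bond$acceptor))
}

#' Per-residue hydrogen-bond statistics over a trajectory
#'
#' Per frame, bonds of each class are counted and divided by the number of
#' included residues; `n_exclude` terminal residues at each end contribute
#' neither bonds (any bond touching an excluded residue is dropped) nor
#' denominator. Means and standard deviations are taken over frames.
#'
#' @param traj a `Trajectory`.
#' @param model the `PeptideModel` (defaults to `traj$model`).
#' @param n_exclude terminal residues excluded at each end.
#' @param dist_cutoff,angle_cutoff geometric criterion, see
#'   [detect_hbonds()].
#' @return an `HBondStats`: list with `mean`, `sd` (named by class,
#'   per-residue units), `per_frame` (data frame of per-frame per-residue
#'   counts), `n_residues_included`.
#' @export
per_residue_hbond_stats <- function(traj, model = traj$model, n_exclude = 0,
                                    dist_cutoff = 0.35, angle_cutoff = 30) {
  stopifnot(inherits(traj, "Trajectory"))
  if (length(traj$frames) < 1) stop("trajectory is empty")
  n <- model$n_residues
  incl <- setdiff(seq_len(n),
                  c(seq_len(n_exclude), n - seq_len(n_exclude) + 1))
  if (length(incl) < 1) stop("n_exclude leaves no residues")
  classes <- c("BB", "BW", "BS", "other")
  per <- t(vapply(traj$frames, function(fr) {
    b <- detect_hbonds(fr, model, dist_cutoff, angle_cutoff)
    if (nrow(b) > 0) {
      rd <- model$atoms$residue[ifelse(b$donor <= nrow(model$atoms),
                                       b$donor, NA)]
      ra <- model$atoms$residue[ifelse(b$acceptor <= nrow(model$atoms),
                                       b$acceptor, NA)]
      drop_bond <- (!is.na(rd) & !(rd %in% incl)) |
        (!is.na(ra) & !(ra %in% incl))
      b <- b[!drop_bond, , drop = FALSE]
    }
    counts <- vapply(classes, function(cl) sum(b$class == cl), numeric(1))
    counts / length(incl)
  }, numeric(4)))
  colnames(per) <- classes
  structure(list(
    mean = colMeans(per),
    sd = apply(per, 2, stats::sd),
    per_frame = as.data.frame(per),
    n_residues_included = length(incl)), class = "HBondStats")
}

#' Count dangling backbone N-H and C=O groups
#'
#' Backbone amide groups taking part in no intra-backbone hydrogen bond
#' under the geometric criterion. On an ideal helix the first four N-H
#' (no i-4 partner) and last four C=O (no i+4 partner) dangle.
#'
#' @param conf a `Conformation` (water ignored; backbone-backbone bonds
#'   only).
#' @param model the `PeptideModel`.
#' @param dist_cutoff,angle_cutoff geometric criterion.
#' @return integer vector `c(free_NH = ..., free_CO = ...)`.
#' @export
count_dangling_backbone_groups <- function(conf, model,
                                           dist_cutoff = 0.35,
                                           angle_cutoff = 30) {
  if (inherits(conf, "Frame")) conf <- conf$conf
  b <- detect_hbonds(conf, model, dist_cutoff, angle_cutoff)
  bb <- b[b$class == "BB", , drop = FALSE]
  don_res <- unique(model$atoms$residue[bb$donor])
  acc_res <- unique(model$atoms$residue[bb$acceptor])
  c(free_NH = model$n_residues - length(don_res),
    free_CO = model$n_residues - length(acc_res))
}
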