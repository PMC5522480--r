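# File formats: multi-model PDB for trajectories (bio3d backend),
# whitespace-delimited 3-column ASCII for SANS curves, JSON reports.

#' Write a trajectory as a multi-model PDB file
#'
#' One MODEL record per frame, CRYST1 for the box, chain A for the
#' peptide, residue name HOH for waters. Coordinates are converted from nm
#' to Angstrom.
#'
#' @param traj a `Trajectory`.
#' @param path output file.
#' @export
write_trajectory_pdb <- function(traj, path) {
  stopifnot(inherits(traj, "Trajectory"))
  model <- traj$model
  con <- file(path, "w")
  on.exit(close(con))
  box <- traj$frames[[1]]$box * 10
  writeLines(sprintf(
    "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1", box, box, box,
    90, 90, 90), con)
  for (fi in seq_along(traj$frames)) {
    fr <- traj$frames[[fi]]
    writeLines(sprintf("MODEL     %4d", fi), con)
    at <- model$atoms
    xyz <- fr$conf$xyz * 10
    serial <- 0L
    for (i in seq_len(nrow(at))) {
      serial <- serial + 1L
      writeLines(sprintf(
        "ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, substr(at$name[i], 1, 4), "PEP", "A", at$residue[i],
        xyz[i, 1], xyz[i, 2], xyz[i, 3], 1, 0, at$element[i]), con)
    }
    if (nrow(fr$water_o) > 0) {
      for (w in seq_len(nrow(fr$water_o))) {
        o <- fr$water_o[w, ] * 10
        h <- fr$water_h[(2 * w - 1):(2 * w), , drop = FALSE] * 10
        for (row in list(c("O", o), c("H1", h[1, ]), c("H2", h[2, ]))) {
          serial <- serial + 1L
          writeLines(sprintf(
            "ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial, row[1], "HOH", "W", w,
            as.numeric(row[2]), as.numeric(row[3]), as.numeric(row[4]),
            1, 0, substr(row[1], 1, 1)), con)
        }
      }
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB trajectory written by [write_trajectory_pdb()]
#'
#' @param path PDB file.
#' @param model the `PeptideModel` the peptide records correspond to.
#' @param time_step frame spacing, ns.
#' @return a `Trajectory` (coordinates in nm).
#' @export
read_trajectory_pdb <- function(path, model, time_step = 0.1) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  xyz <- pdb$xyz                       # matrix: frames x (3 natoms), Angstrom
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  is_pep <- pdb$atom$resid != "HOH"
  np <- sum(is_pep)
  if (np != nrow(model$atoms))
    stop("PDB peptide atom count does not match the model")
  box <- NULL
  cl <- grep("^CRYST1", readLines(path, n = 5), value = TRUE)
  if (length(cl)) box <- as.numeric(substr(cl[1], 7, 15)) / 10
  nw <- sum(!is_pep) / 3
  frames <- lapply(seq_len(nrow(xyz)), function(fi) {
    m <- matrix(xyz[fi, ], ncol = 3, byrow = TRUE) / 10
    conf <- new_conformation(m[which(is_pep), , drop = FALSE], model)
    wat <- m[which(!is_pep), , drop = FALSE]
    if (nw > 0) {
      o_idx <- seq(1, 3 * nw, by = 3)
      water_o <- wat[o_idx, , drop = FALSE]
      water_h <- wat[-o_idx, , drop = FALSE]
    } else {
      water_o <- matrix(numeric(0), 0, 3)
      water_h <- matrix(numeric(0), 0, 3)
    }
    structure(list(conf = conf, water_o = water_o, water_h = water_h,
                   box = box, time = (fi - 1) * time_step),
              class = "Frame")
  })
  structure(list(frames = frames, time_step = time_step, model = model,
                 kind = "file"), class = "Trajectory")
}

#' Write a SANS curve as 3-column ASCII
#'
#' Whitespace-delimited `q I sigma` with `#` header lines carrying the
#' D2O fraction and column names.
#'
#' @param curve a `SANSCurve`.
#' @param path output file.
#' @export
write_sans_curve <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  f <- attr(curve, "d2o_fraction")
  if (!is.null(f) && !is.na(f))
    writeLines(sprintf("# d2o_fraction=%g", f), con)
  writeLines("# q[1/A] I[1/cm] sigma[1/cm]", con)
  utils::write.table(curve[, c("q", "I", "sigma")], con,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a 3-column ASCII SANS curve
#'
#' @param path input file; `#` lines are comments, a
#'   `# d2o_fraction=<f>` line tags the solvent contrast.
#' @return a `SANSCurve`.
#' @export
read_sans_curve <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^\\s*#", lines, value = TRUE)
  f <- NA_real_
  tag <- grep("d2o_fraction\\s*=", hdr, value = TRUE)
  if (length(tag))
    f <- as.numeric(sub(".*d2o_fraction\\s*=\\s*([0-9.eE+-]+).*", "\\1",
                        tag[1]))
  dat <- utils::read.table(text = lines, comment.char = "#")
  if (ncol(dat) < 3) stop("expected 3 columns: q I sigma")
  new_sans_curve(dat[[1]], dat[[2]], dat[[3]], f)
}

#' Write a contrast series to a directory
#' @param series a `ContrastSeries`.
#' @param dir output directory (created if missing).
#' @export
write_contrast_series <- function(series, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_along(series$curves)) {
    f <- attr(series$curves[[i]], "d2o_fraction")
    write_sans_curve(series$curves[[i]],
                     file.path(dir, sprintf("contrast_d2o_%03d.dat",
                                            round(100 * f))))
  }
  invisible(dir)
}

#' Read every 3-column ASCII curve in a directory as a contrast series
#' @param dir directory of `.dat` files written by [write_sans_curve()].
#' @return a `ContrastSeries` (without planted truth).
#' @export
read_contrast_series <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.dat$", full.names = TRUE))
  if (!length(files)) stop("no .dat curves in ", dir)
  structure(list(curves = lapply(files, read_sans_curve), truth = NULL),
            class = "ContrastSeries")
}
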