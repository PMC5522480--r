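# Pipeline orchestration: validated configuration, staged analysis runs,
# titration fitting, JSON reports.

default_conformation_config <- function() {
  list(
    input = list(pdb = NULL, time_step = 0.1),
    synthetic = list(n_residues = 10, ligand = "triazole",
                     protonated = TRUE, kind = "stable_helix",
                     n_frames = 50, time_step = 0.1, seed = 1,
                     amplitude = 0.02, n_waters = 0, box_edge = 6,
                     depletion_radius = NULL),
    helix = list(n_exclude = 2, ideal_radius = 0.23, ideal_twist = 100,
                 ideal_rise = 0.15),
    hbonds = list(dist_cutoff = 0.35, angle_cutoff = 30, n_exclude = 0),
    rdf = list(bin_width = 0.04, r_max = NULL, n_blocks = 5,
               depletion_threshold = 0.1)
  )
}

default_sans_config <- function() {
  list(
    input = list(dir = NULL),
    synthetic = list(preset = "pH2", relative_noise = 0.02, seed = 1),
    powerlaw = list(q_window = c(0.006, 0.017)),
    fit = list(shared = c("radius", "length", "power_exp"),
               per_curve = c("sld_particle", "power_amp", "background"),
               n_starts = 5, seed = 1,
               init = list(radius = 15, length = 60, power_amp = 1e-6,
                           power_exp = 3.6, background = 0.005,
                           phi = 0.005, charge = 20, screening = 30))
  )
}

# merge user config into defaults, rejecting unknown keys at both levels
merge_config <- function(defaults, config) {
  for (sec in names(config)) {
    if (!sec %in% names(defaults))
      stop("unknown config section: ", sec)
    if (is.list(config[[sec]]) && is.list(defaults[[sec]])) {
      bad <- setdiff(names(config[[sec]]), names(defaults[[sec]]))
      if (length(bad))
        stop("unknown config key(s) in ", sec, ": ", paste(bad, collapse = ", "))
      defaults[[sec]][names(config[[sec]])] <- config[[sec]]
    } else defaults[[sec]] <- config[[sec]]
  }
  defaults
}

#' Run the conformation analysis pipeline
#'
#' Executes, in order: helix-geometry fitting (per-frame RMSD trace plus a
#' full fit of the final frame), hydrogen-bond partition statistics, and
#' (when the trajectory is solvated) the block-averaged hydration RDF with
#' depletion-zone detection. The trajectory is read from
#' `config$input$pdb` or generated by the synthetic module per
#' `config$synthetic`. Stage failures are recorded in the report rather
#' than aborting the run.
#'
#' @param config nested list; see `helicoil:::default_conformation_config()`
#'   for sections and defaults. Unknown keys are rejected.
#' @return a `Report`: list with `config` (fully resolved), `stages`
#'   (per-stage results or error messages), `ok`.
#' @export
run_conformation_pipeline <- function(config = list()) {
  cfg <- merge_config(default_conformation_config(), config)
  stages <- list()
  traj <- if (!is.null(cfg$input$pdb)) {
    if (!file.exists(cfg$input$pdb))
      stop("trajectory file not found: ", cfg$input$pdb)
    sc <- cfg$synthetic
    model <- build_topology(sc$n_residues, sc$ligand, sc$protonated)
    read_trajectory_pdb(cfg$input$pdb, model, cfg$input$time_step)
  } else {
    sc <- cfg$synthetic
    model <- build_topology(sc$n_residues, sc$ligand, sc$protonated)
    generate_trajectory(model, sc$kind, sc$n_frames, sc$time_step, sc$seed,
                        amplitude = sc$amplitude, n_waters = sc$n_waters,
                        box_edge = sc$box_edge,
                        depletion_radius = sc$depletion_radius)
  }
  run_stage <- function(name, expr) {
    stages[[name]] <<- tryCatch(expr, error = function(e)
      list(error = conditionMessage(e)))
  }
  hx <- cfg$helix
  run_stage("helix", {
    trace <- rmsd_time_trace(traj, hx$ideal_radius, hx$ideal_twist,
                             hx$ideal_rise, hx$n_exclude)
    fit <- fit_helix(traj$frames[[length(traj$frames)]]$conf,
                     n_exclude = hx$n_exclude)
    list(rmsd_trace = trace, mean_rmsd = mean(trace$rmsd, na.rm = TRUE),
         sd_rmsd = stats::sd(trace$rmsd, na.rm = TRUE), final_fit = fit,
         helical = is.finite(fit$rmsd_helix) && !fit$degenerate &&
           fit$rmsd_helix <= 0.1)
  })
  hb <- cfg$hbonds
  run_stage("hbonds", per_residue_hbond_stats(traj, traj$model,
                                              hb$n_exclude, hb$dist_cutoff,
                                              hb$angle_cutoff))
  if (nrow(traj$frames[[1]]$water_o) > 0) {
    rd <- cfg$rdf
    run_stage("rdf", {
      rdf <- block_average_rdf(traj, traj$model, rd$n_blocks, rd$bin_width,
                               rd$r_max)
      list(rdf = rdf,
           depletion_radius = depletion_radius(rdf, rd$depletion_threshold))
    })
  }
  structure(list(config = cfg, stages = stages,
                 ok = !any(vapply(stages, function(s)
                   is.list(s) && !is.null(s$error), logical(1)))),
            class = "Report")
}

#' Run the SANS analysis pipeline
#'
#' Executes, in order: per-curve low-q power-law characterization, the
#' simultaneous multi-contrast fit, and the SLD-vs-solvent regression
#' yielding the particle water volume fraction. Curves come from
#' `config$input$dir` (3-column ASCII) or the synthetic contrast series
#' per `config$synthetic`.
#'
#' @param config nested list; see `helicoil:::default_sans_config()`.
#' @return a `Report` with stages `powerlaw`, `joint_fit`,
#'   `water_fraction`.
#' @export
run_sans_pipeline <- function(config = list()) {
  cfg <- merge_config(default_sans_config(), config)
  series <- if (!is.null(cfg$input$dir)) read_contrast_series(cfg$input$dir)
  else {
    sc <- cfg$synthetic
    simulate_contrast_series(preset = sc$preset,
                             relative_noise = sc$relative_noise,
                             seed = sc$seed)
  }
  if (length(series$curves) < 2) stop("need at least 2 contrast curves")
  stages <- list()
  stages$powerlaw <- lapply(series$curves, function(cu)
    tryCatch(fit_powerlaw_exponent(cu, cfg$powerlaw$q_window),
             error = function(e) list(error = conditionMessage(e))))
  fit_cfg <- cfg$fit
  init <- do.call(sans_model_params, fit_cfg$init)
  stages$joint_fit <- tryCatch(
    fit_contrast_series(series, init, fit_cfg$shared, fit_cfg$per_curve,
                        fit_cfg$n_starts, fit_cfg$seed),
    error = function(e) list(error = conditionMessage(e)))
  stages$water_fraction <- if (is.null(stages$joint_fit$error)) {
    pc <- stages$joint_fit$per_curve
    tryCatch(water_fraction_from_slds(pc$sld_particle, pc$sld_solvent),
             error = function(e) list(error = conditionMessage(e)))
  } else list(error = "joint fit failed")
  structure(list(config = cfg, stages = stages,
                 ok = !any(vapply(stages, function(s)
                   is.list(s) && !is.null(s$error), logical(1)))),
            class = "Report")
}

#' Fit a pKa to a titration curve
#'
#' Least-squares fit of the Henderson-Hasselbalch protonated fraction
#' `f(pH) = 1 / (1 + 10^(pH - pKa))` with pKa the single free parameter.
#' Flat data (no transition inside the pH range) and fractions that rise
#' with pH (non-physical for an acid) are flagged.
#'
#' @param curve a `TitrationCurve` (data frame with `pH`, `fraction`).
#' @return list with `pka`, `se`, `converged`, `flag` (`"ok"`,
#'   `"no_transition"` or `"non_physical"`).
#' @export
fit_pka <- function(curve) {
  if (nrow(curve) < 4) stop("need at least 4 titration points")
  f <- curve$fraction; pH <- curve$pH
  flag <- "ok"
  if (diff(range(f)) < 0.2) flag <- "no_transition"
  else if (stats::cor(pH, f) > 0) flag <- "non_physical"
  start <- pH[which.min(abs(f - 0.5))]
  obj <- function(p) sum((f - 1 / (1 + 10^(pH - p)))^2)
  opt <- stats::optim(start, obj, method = "Brent",
                      lower = min(pH) - 5, upper = max(pH) + 5)
  # 1-sigma from the curvature of the least-squares surface
  h <- 1e-4
  d2 <- (obj(opt$par + h) - 2 * opt$value + obj(opt$par - h)) / h^2
  dof <- max(nrow(curve) - 1, 1)
  se <- if (d2 > 0) sqrt(2 * opt$value / dof / d2) else NA_real_
  list(pka = opt$par, se = se, converged = opt$convergence == 0,
       flag = flag)
}

#' Serialize a pipeline report to JSON
#'
#' @param report a `Report`.
#' @param path output file.
#' @export
write_report_json <- function(report, path) {
  simplify <- function(x) {
    if (inherits(x, "FitResult"))
      x <- list(estimates = as.list(x$estimates), se = as.list(x$se),
                redchi2 = x$redchi2, converged = x$converged,
                per_curve = x$per_curve)
    if (inherits(x, "HelixFit")) x <- unclass(x)
    if (inherits(x, "WaterFractionResult")) x <- unclass(x)
    if (inherits(x, "HBondStats"))
      x <- list(mean = as.list(x$mean), sd = as.list(x$sd),
                n_residues_included = x$n_residues_included)
    if (is.data.frame(x)) return(x)
    if (is.list(x)) return(lapply(x, simplify))
    x
  }
  jsonlite::write_json(simplify(unclass(report)), path, auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  invisible(path)
}
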