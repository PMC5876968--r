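#' Configuration of an end-to-end spray run
#'
#' Bundles every knob of the injection -> transport -> breakup -> outlet
#' pipeline.  Defaults follow the study conditions: outlet plane at 60 mm
#' (PFD) or 52 mm (FC75) from the catheter tip, time-step 1e-4 s, 500
#' parcels per step, 0.06 s of simulated time with outlet statistics taken
#' over the final 0.01 s analysis window.
#'
#' @param compound "PFD" or "FC75".
#' @param pressure 4 or 5 (bar).
#' @param domain_length m; default 0.060 for PFD, 0.052 for FC75.
#' @param dt s time-step (default 1e-4).
#' @param parcels_per_step default 500.
#' @param duration s simulated (default 0.06).
#' @param analysis_window s at the end of the run over which outlet
#'   statistics are computed (default 0.01).
#' @param seed integer RNG seed (default 1).
#' @param output_dir optional directory for result files.
#' @param breakup_enabled,turbulence_enabled logical switches (default TRUE).
#' @param injection_line_length m (default 1e-4).
#' @param jet named list of [jet_flow_config()] overrides.
#' @param props optional [compound_properties()] override.
#' @param tab [tab_constants()].
#' @return Object of class `run_config`.
#' @export
run_config <- function(compound = "PFD", pressure = 4,
                       domain_length = NULL, dt = 1e-4,
                       parcels_per_step = 500L, duration = 0.06,
                       analysis_window = 0.01, seed = 1L,
                       output_dir = NULL, breakup_enabled = TRUE,
                       turbulence_enabled = TRUE,
                       injection_line_length = 1e-4,
                       jet = list(), props = NULL, tab = tab_constants()) {
  compound <- match.arg(compound, c("PFD", "FC75"))
  if (!pressure %in% c(4, 5)) stop("pressure must be 4 or 5 bar")
  if (is.null(domain_length))
    domain_length <- if (compound == "PFD") 0.060 else 0.052
  if (analysis_window > duration)
    stop("analysis_window cannot exceed duration")
  structure(list(compound = compound, pressure = pressure,
                 domain_length = domain_length, dt = dt,
                 parcels_per_step = as.integer(parcels_per_step),
                 duration = duration, analysis_window = analysis_window,
                 seed = as.integer(seed), output_dir = output_dir,
                 breakup_enabled = breakup_enabled,
                 turbulence_enabled = turbulence_enabled,
                 injection_line_length = injection_line_length,
                 jet = jet, props = props, tab = tab),
            class = "run_config")
}

#' Run the full aerosol-delivery pipeline
#'
#' Composes the packaged injection table, the calibrated surrogate jet, the
#' Lagrangian transport/breakup solver and the aerosol statistics:
#' simulates the spray, collects outlet crossings over the analysis window,
#' and derives the cumulative mass distribution, the aerosol summary
#' (geometric and aerodynamic mass medians, GSD) and a mass-balance report.
#' With `output_dir` set, writes `outlet_records.csv`, `ydg_curve.csv`,
#' `summary.json`, `mass_balance.json` and `run.log`; all outputs are
#' regenerable bit-exactly from `(config, seed)`.
#'
#' @param config a [run_config()].
#' @param table optional [injection_table()] override (default: the
#'   packaged table for the configured scenario).
#' @return List of class `spray_run`: `sim` (the [simulate_spray()]
#'   result), `ydg` (cumulative mass curve at the outlet), `summary`,
#'   `mass_balance`, `config`.
#' @export
run_spray <- function(config, table = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(table)) table <- load_injection_table(config$compound, config$pressure)
  jet_args <- utils::modifyList(
    list(driving_pressure = config$pressure, domain_length = config$domain_length),
    config$jet)
  flow <- do.call(jet_flow_config, jet_args)
  props <- if (is.null(config$props)) compound_properties(config$compound)
           else config$props

  sim <- simulate_spray(table, flow, props,
                        duration = config$duration, dt = config$dt,
                        parcels_per_step = config$parcels_per_step,
                        seed = config$seed,
                        breakup_enabled = config$breakup_enabled,
                        turbulence_enabled = config$turbulence_enabled,
                        tab = config$tab,
                        injection_line_length = config$injection_line_length)

  w0 <- sim$duration - config$analysis_window
  win <- sim$outlet[sim$outlet$time_s >= w0, , drop = FALSE]
  if (nrow(win) == 0)
    stop("transport stage produced no outlet crossings in the analysis window")
  ydg <- cumulative_mass_distribution(win$diameter_um, win$mass_kg)
  dist <- as_size_distribution(win$diameter_um, win$mass_kg)
  mmgd <- mmad(dist)
  summary <- list(
    MMGD_um = mmgd,
    MMAD_um = geometric_to_aerodynamic(mmgd, props$liquid_density / 1000),
    GSD = gsd(dist),
    heterodisperse = gsd(dist) > 1.25,
    max_weber = sim$max_weber,
    n_outlet_parcels = nrow(win))
  mb <- mass_balance(sim, config$analysis_window)

  out <- structure(list(sim = sim, ydg = ydg, summary = summary,
                        mass_balance = mb, config = config),
                   class = "spray_run")
  if (!is.null(config$output_dir)) write_run_outputs(out, config$output_dir)
  out
}

#' Mass-balance report of a spray run
#'
#' Compares the time-averaged outlet particle mass flow over the final
#' `window` seconds with the injected mass flow (the two must match under
#' mass conservation once the run is quasi-steady), and reports the rms of
#' the per-step outlet flux about the injected value -- the step-to-step
#' imbalance that shrinks as more parcels per step are used.
#'
#' @param sim a [simulate_spray()] result.
#' @param window s, averaging window at the end of the run.
#' @return List with `inlet_kg_s`, `outlet_kg_s`, `ratio`,
#'   `rms_step_imbalance_kg_s`, `rms_relative`, `window_s`.
#' @export
mass_balance <- function(sim, window = 0.01) {
  stopifnot(inherits(sim, "spray_result"))
  w0 <- sim$duration - window
  sl <- sim$step_log[sim$step_log$time_s > w0 + 1e-12, , drop = FALSE]
  flux <- sl$outlet_mass_kg / sim$dt
  inlet <- sim$injected_mass_flow
  outlet <- sum(sl$outlet_mass_kg) / (nrow(sl) * sim$dt)
  list(inlet_kg_s = inlet, outlet_kg_s = outlet, ratio = outlet / inlet,
       rms_step_imbalance_kg_s = sqrt(mean((flux - inlet)^2)),
       rms_relative = sqrt(mean((flux / inlet - 1)^2)),
       window_s = window)
}

#' @export
print.spray_run <- function(x, ...) {
  print(x$sim)
  cat(sprintf("  outlet MMGD %.3g um, MMAD %.3g um, GSD %.3g\n",
              x$summary$MMGD_um, x$summary$MMAD_um, x$summary$GSD))
  cat(sprintf("  mass balance outlet/inlet = %.4f over final %g s\n",
              x$mass_balance$ratio, x$mass_balance$window_s))
  invisible(x)
}

write_run_outputs <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$sim$outlet, file.path(dir, "outlet_records.csv"),
                   row.names = FALSE)
  utils::write.csv(run$ydg, file.path(dir, "ydg_curve.csv"), row.names = FALSE)
  jsonlite::write_json(run$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(run$mass_balance, file.path(dir, "mass_balance.json"),
                       auto_unbox = TRUE, digits = NA)
  cfg <- run$config
  writeLines(c(sprintf("compound=%s pressure=%g bar", cfg$compound, cfg$pressure),
               sprintf("seed=%d", cfg$seed),
               sprintf("dt=%g duration=%g parcels_per_step=%d",
                       cfg$dt, cfg$duration, cfg$parcels_per_step),
               sprintf("domain_length=%g analysis_window=%g",
                       cfg$domain_length, cfg$analysis_window),
               sprintf("breakup=%s turbulence=%s",
                       cfg$breakup_enabled, cfg$turbulence_enabled),
               sprintf("config_hash=%s", {
                 phys <- unclass(cfg)
                 phys$output_dir <- NULL   # not part of the physics
                 format(sum(utf8ToInt(paste(deparse(phys), collapse = ""))),
                        scientific = FALSE)
               })),
             file.path(dir, "run.log"))
  invisible(dir)
}

#' Compare two cumulative mass distributions
#'
#' Evaluates both curves on the union of their diameter grids (linear
#' interpolation, clamped to [0, 1]) and reports the maximum absolute
#' deviation plus the difference in mass fraction carried by particles
#' above the 3, 5 and 10 um discussion cut-points.
#'
#' @param simulated,reference data frames with `diameter_um` and
#'   `cum_fraction` (normalized: non-decreasing, ending at 1).
#' @param cutpoints_um diameters at which above-size mass fractions are
#'   compared (default `c(3, 5, 10)`).
#' @return List with `max_abs_deviation` and a data frame
#'   `cutpoint_differences` (`diameter_um`, `simulated_above`,
#'   `reference_above`, `difference`).
#' @export
compare_distributions <- function(simulated, reference,
                                  cutpoints_um = c(3, 5, 10)) {
  check_curve <- function(cv, nm) {
    if (!all(c("diameter_um", "cum_fraction") %in% names(cv)))
      stop(nm, " needs columns diameter_um and cum_fraction")
    if (is.unsorted(cv$cum_fraction) || is.unsorted(cv$diameter_um))
      stop(nm, " curve must be non-decreasing")
    if (abs(cv$cum_fraction[nrow(cv)] - 1) > 1e-6)
      stop(nm, " curve is not normalized (must end at 1)")
  }
  check_curve(simulated, "simulated"); check_curve(reference, "reference")
  fsim <- stats::approxfun(simulated$diameter_um, simulated$cum_fraction,
                           yleft = 0, yright = 1, ties = "ordered")
  fref <- stats::approxfun(reference$diameter_um, reference$cum_fraction,
                           yleft = 0, yright = 1, ties = "ordered")
  grid <- sort(unique(c(simulated$diameter_um, reference$diameter_um)))
  dev <- abs(fsim(grid) - fref(grid))
  above <- data.frame(diameter_um = cutpoints_um,
                      simulated_above = 1 - fsim(cutpoints_um),
                      reference_above = 1 - fref(cutpoints_um))
  above$difference <- above$simulated_above - above$reference_above
  list(max_abs_deviation = max(dev), cutpoint_differences = above)
}
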