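#' Default run configuration
#'
#' All pipeline settings with their defaults: a 40 mm radius, 120 mm long
#' layered forearm phantom at 1 mm spacing; 3 mm radius gel electrodes 2 cm
#' apart; median/radial/ulnar trajectories at 5.5/13.1/14.9 mm; the five
#' commercial pulse widths; a 5.7 um, 101-node sensory fibre; 5 mA baseline
#' and 1% titration tolerance.
#'
#' @return nested named list (the `RunConfig`).
#' @export
default_config <- function() {
  list(
    phantom = list(radius_mm = 40, length_mm = 120, spacing_mm = 1, pad_mm = 4,
                   layers = list(skin = 1.5, sat = 3.5, muscle = 15),
                   core_tissue = "cortical_bone"),
    electrodes = list(radius_mm = 3, thickness_mm = 2, separation_mm = 20),
    nerves = list(median = 5.5, radial = 13.1, ulnar = 14.9),
    pulses = list(widths_us = c(30, 88, 146, 262, 495), interphase_ms = 0.1,
                  polarity = "cathodic_first"),
    axon = list(diameter_um = 5.7, n_nodes = 101, variant = "sensory"),
    solver = list(tol = 1e-8, maxit = 50000),
    titration = list(baseline_mA = 5, tol = 0.01, t_init = 0.1,
                     max_doublings = 15, duration_ms = 3.5, dt_ms = 0.0025),
    vta = list(reference_nerve = "median"),
    seed = 1,
    write_fields = FALSE,
    output_dir = NULL
  )
}

.validate_config <- function(cfg) {
  def <- default_config()
  unknown <- setdiff(names(cfg), names(def))
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  for (sec in names(cfg)) {
    if (is.list(def[[sec]]) && !is.null(names(def[[sec]])) && is.list(cfg[[sec]])) {
      bad <- setdiff(names(cfg[[sec]]), names(def[[sec]]))
      if (length(bad) && sec != "nerves")
        stop(sprintf("unknown config keys in `%s`: %s", sec, paste(bad, collapse = ", ")))
    }
  }
  out <- def
  for (sec in names(cfg)) {
    out[[sec]] <- if (is.list(def[[sec]]) && sec != "nerves")
      modifyList(def[[sec]], as.list(cfg[[sec]])) else cfg[[sec]]
  }
  if (length(out$pulses$widths_us) < 1) stop("pulses$widths_us must be non-empty")
  if (!out$vta$reference_nerve %in% names(out$nerves))
    stop("vta$reference_nerve must be one of the configured nerves")
  out
}

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON) configuration, fills defaults and validates it;
#' unknown keys are rejected by name.
#'
#' @param path YAML or JSON file; alternatively a named list.
#' @return validated `RunConfig` list.
#' @export
load_config <- function(path) {
  cfg <- if (is.list(path)) path
         else if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  .validate_config(cfg)
}

#' Serialize a configuration to YAML
#' @param config a `RunConfig` list.
#' @param path output file.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# content hash for provenance (polynomial rolling hash over serialized bytes,
# kept below 2^53 so double arithmetic stays exact)
.config_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  h <- 17
  for (b in as.integer(raw)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full dosimetry pipeline
#'
#' Phantom construction, one unit field solve per montage, per-nerve
#' extracellular sampling, titration at every pulse width (strength-duration
#' curves with Weiss and Lapicque fits for the reference nerve), AF threshold
#' calibration per pulse width, and VTA volume/depth at the common evaluation
#' current (the mean of the shortest- and longest-pulse thresholds of the
#' reference nerve), with a linear VTA-vs-PW fit. Deterministic for a fixed
#' configuration.
#'
#' @param config a `RunConfig` list or a path accepted by [load_config()].
#' @param verbose print stage progress.
#' @return a `run_report` list (tables, fits, provenance).
#' @export
run_pipeline <- function(config = default_config(), verbose = FALSE) {
  cfg <- if (is.list(config) ) .validate_config(config) else load_config(config)
  set.seed(cfg$seed)
  t0 <- proc.time()[["elapsed"]]
  say <- function(...) if (verbose) message(sprintf(...))
  timings <- c()
  stage <- function(name, expr) {
    s <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr),
                    error = function(e) stop(sprintf("stage `%s` failed: %s",
                                                     name, conditionMessage(e)),
                                             call. = FALSE))
    timings[[name]] <<- proc.time()[["elapsed"]] - s
    say("stage %-12s %.1fs", name, timings[[name]])
    out
  }

  grid <- stage("phantom", {
    g <- do.call(build_phantom, c(cfg$phantom[setdiff(names(cfg$phantom), "layers")],
                                  list(layers = unlist(cfg$phantom$layers))))
    place_electrodes(g, default_montage(g, cfg$electrodes$separation_mm,
                                        cfg$electrodes$radius_mm,
                                        cfg$electrodes$thickness_mm))
  })
  pot_unit <- stage("solve", solve_potential(grid, voltage = 1,
                                             tol = cfg$solver$tol,
                                             maxit = cfg$solver$maxit))
  cur <- electrode_current(pot_unit)
  pot_base <- scale_to_current(pot_unit, cfg$titration$baseline_mA)
  axon <- build_axon(cfg$axon$diameter_um, cfg$axon$n_nodes, cfg$axon$variant)

  sd_rows <- list(); sd_curves <- list()
  stage("titration", {
    for (nerve in names(cfg$nerves)) {
      traj <- make_nerve_trajectory(grid, nerve, cfg$nerves[[nerve]],
                                    spacing_mm = axon$internode_um / 1000)
      drv <- sample_extracellular(pot_base, traj, axon)
      sc <- sd_curve(axon, drv, cfg$pulses$widths_us,
                     baseline_mA = cfg$titration$baseline_mA,
                     interphase_ms = cfg$pulses$interphase_ms,
                     polarity = cfg$pulses$polarity,
                     tol = cfg$titration$tol, t_init = cfg$titration$t_init,
                     max_doublings = cfg$titration$max_doublings,
                     duration_ms = cfg$titration$duration_ms,
                     dt_ms = cfg$titration$dt_ms)
      sd_curves[[nerve]] <- sc
      sd_rows[[nerve]] <- cbind(nerve = nerve, sc$table)
    }
    NULL
  })
  sd_table <- do.call(rbind, sd_rows)
  rownames(sd_table) <- NULL

  ref <- cfg$vta$reference_nerve
  ref_tab <- sd_curves[[ref]]$table
  fits <- lapply(c(weiss = "weiss", lapicque = "lapicque"), function(f)
    tryCatch(fit_sd(sd_curves[[ref]], f), error = function(e) NULL))
  thr_short <- ref_tab$threshold_mA[which.min(ref_tab$pw_us)]
  thr_long <- ref_tab$threshold_mA[which.max(ref_tab$pw_us)]
  common_mA <- common_evaluation_current(c(thr_short, thr_long))

  vta_results <- stage("af_vta", {
    af_unit <- hessian_af(pot_unit)
    ref_traj <- make_nerve_trajectory(grid, ref, cfg$nerves[[ref]],
                                      spacing_mm = axon$internode_um / 1000)
    lapply(seq_len(nrow(ref_tab)), function(i) {
      thr <- calibrate_af_threshold(rescale_af(af_unit, ref_tab$threshold_mA[i]),
                                    ref_traj)
      thr$pw_us <- ref_tab$pw_us[i]
      vta(rescale_af(af_unit, common_mA), thr, grid)
    })
  })
  vta_table <- data.frame(
    pw_us = sapply(vta_results, `[[`, "pw_us"),
    threshold_current_mA = ref_tab$threshold_mA,
    af_threshold_V_per_m2 = sapply(vta_results, `[[`, "threshold"),
    volume_mm3 = sapply(vta_results, `[[`, "volume_mm3"),
    depth_mm = sapply(vta_results, `[[`, "depth_mm"))
  linfit <- if (nrow(vta_table) >= 3) vta_vs_pw(vta_results) else NULL

  report <- structure(list(
    config = cfg, config_hash = .config_hash(cfg), seed = cfg$seed,
    package_version = as.character(utils::packageVersion("tensdepth")),
    unit_voltage_V = 1, unit_current_mA = cur$anode_mA,
    current_imbalance = cur$imbalance, solver_iterations = pot_unit$iterations,
    sd_table = sd_table, sd_fits = fits, common_current_mA = common_mA,
    vta_table = vta_table, vta_fit = linfit,
    timings_s = timings, total_s = proc.time()[["elapsed"]] - t0
  ), class = "run_report")
  report$objects <- list(grid = grid, potential_unit = pot_unit,
                         sd_curves = sd_curves, vta_results = vta_results)
  if (!is.null(cfg$output_dir)) write_outputs(report, cfg$output_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> hash %s | unit current %.4g mA | common current %.4g mA\n",
              x$config_hash, x$unit_current_mA, x$common_current_mA))
  cat("strength-duration table:\n"); print(x$sd_table, row.names = FALSE)
  cat("VTA table:\n"); print(x$vta_table, row.names = FALSE)
  if (!is.null(x$vta_fit)) print(x$vta_fit)
  invisible(x)
}

#' Common evaluation current
#'
#' The single current at which VTA maps are compared across pulse widths: the
#' arithmetic mean of the thresholds at the shortest and longest pulse width.
#'
#' @param x an `sd_curve`, or a numeric vector of two thresholds (mA).
#' @return current in mA.
#' @export
#' @examples
#' common_evaluation_current(c(19.7, 1.75))
common_evaluation_current <- function(x) {
  if (inherits(x, "sd_curve")) {
    tab <- x$table
    x <- c(tab$threshold_mA[which.min(tab$pw_us)],
           tab$threshold_mA[which.max(tab$pw_us)])
  }
  stopifnot(is.numeric(x), length(x) == 2)
  mean(x)
}

#' Write pipeline outputs
#'
#' Writes `sd.csv` (per-nerve strength-duration table), `vta.csv` (per-PW
#' VTA table), and `report.json`; optionally the potential and field
#' magnitude as legacy-ASCII VTK structured points when the report was run
#' with `write_fields = TRUE`.
#'
#' @param report a `run_report`.
#' @param dir output directory (created if missing).
#' @return invisibly, the files written.
#' @export
write_outputs <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(dir, 2) != 0) stop("output directory is not writable: ", dir)
  files <- c(sd = file.path(dir, "sd.csv"), vta = file.path(dir, "vta.csv"),
             report = file.path(dir, "report.json"))
  .write_table_full(report$sd_table, files["sd"])
  .write_table_full(report$vta_table, files["vta"])
  fits <- lapply(report$sd_fits, function(f) if (is.null(f)) NULL else
    list(form = f$form, rheobase_mA = f$rheobase_mA, chronaxie_us = f$chronaxie_us))
  js <- list(config_hash = report$config_hash, seed = report$seed,
             package_version = report$package_version,
             units = list(pulse_width = "us", current = "mA", volume = "mm3",
                          depth = "mm", af_threshold = "V/m^2"),
             unit_current_mA = report$unit_current_mA,
             current_imbalance = report$current_imbalance,
             common_current_mA = report$common_current_mA,
             sd_fits = fits,
             vta_fit = if (is.null(report$vta_fit)) NULL else
               report$vta_fit[c("slope_mm3_per_us", "intercept_mm3", "r_squared")],
             sd_table = report$sd_table, vta_table = report$vta_table,
             timings_s = as.list(report$timings_s))
  jsonlite::write_json(js, files["report"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (isTRUE(report$config$write_fields) && !is.null(report$objects)) {
    pot <- report$objects$potential_unit
    write_vtk(pot$phi, pot$grid, file.path(dir, "phi_unit.vtk"), "phi_V")
    ef <- electric_field(pot)
    write_vtk(ef$magnitude, ef$grid, file.path(dir, "emag_unit.vtk"), "E_V_per_m")
    files <- c(files, phi = file.path(dir, "phi_unit.vtk"),
               emag = file.path(dir, "emag_unit.vtk"))
  }
  invisible(files)
}

# CSV with full double precision so round-trips are exact
.write_table_full <- function(tab, path) {
  tab2 <- tab
  for (j in seq_along(tab2)) if (is.numeric(tab2[[j]]))
    tab2[[j]] <- sprintf("%.17g", tab2[[j]])
  write.csv(tab2, path, row.names = FALSE, quote = FALSE)
}

#' Read a strength-duration CSV written by [write_outputs()]
#' @param path path to `sd.csv`.
#' @param nerve optional nerve to select.
#' @return an `sd_curve`.
#' @export
read_sd_curve <- function(path, nerve = NULL) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(nerve)) tab <- tab[tab$nerve == nerve, , drop = FALSE]
  structure(list(table = data.frame(pw_us = tab$pw_us, factor = tab$factor,
                                    threshold_mA = tab$threshold_mA),
                 nerve = if (!is.null(nerve)) nerve else NA,
                 baseline_mA = NA), class = "sd_curve")
}
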