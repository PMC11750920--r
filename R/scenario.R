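# Scenario layer: validated configuration, the standard study grid,
# reproducible on-disk artifacts, and per-breath logging.

#' Simulation scenario
#'
#' Bundles everything one run needs.  The defaults reproduce the standard
#' washout protocol: He tracer in N2 (D = 0.6 cm^2/s), breath period 4 s,
#' peak flow 250 cm^3/s (tidal volume 500 ml), 200 s of simulated time
#' (50 breaths), symmetric geometry, 0.5-ms solver step.
#'
#' @param name Scenario label (used in file names).
#' @param D_cm2_per_s Binary diffusion coefficient.
#' @param T_s Breath period.
#' @param Q_cm3_per_s Peak tracheal flow magnitude.
#' @param duration_s Simulated time.
#' @param asym_area Asymmetry area 1-5, or `NA` for the symmetric model.
#' @param asym_f_c Asymmetry factor in (0, 2).
#' @param dt_s Solver step.
#' @param V_L_ml Target lung volume.
#' @return A validated `scenario` object.
#' @export
scenario <- function(name = "symmetric", D_cm2_per_s = 0.6, T_s = 4,
                     Q_cm3_per_s = 250, duration_s = 200,
                     asym_area = NA, asym_f_c = 1, dt_s = 5e-4,
                     V_L_ml = 3000) {
  bad <- character(0)
  chk <- function(ok, what) if (!isTRUE(ok)) bad <<- c(bad, what)
  chk(is.character(name) && nzchar(name), "name")
  chk(is.numeric(D_cm2_per_s) && D_cm2_per_s > 0, "D_cm2_per_s")
  chk(is.numeric(T_s) && T_s > 0, "T_s")
  chk(is.numeric(Q_cm3_per_s) && Q_cm3_per_s > 0, "Q_cm3_per_s")
  chk(is.numeric(duration_s) && duration_s >= T_s, "duration_s")
  chk(is.na(asym_area) ||
        (asym_area %in% 1:5 && asym_f_c > 0 && asym_f_c < 2),
      "asym_area/asym_f_c")
  chk(is.numeric(dt_s) && dt_s > 0, "dt_s")
  chk(is.numeric(V_L_ml) && V_L_ml > 0, "V_L_ml")
  if (length(bad))
    stop("invalid scenario fields: ", paste(bad, collapse = ", "))
  structure(list(name = name, D_cm2_per_s = D_cm2_per_s, T_s = T_s,
                 Q_cm3_per_s = Q_cm3_per_s, duration_s = duration_s,
                 asym_area = if (is.na(asym_area)) NA_integer_
                             else as.integer(asym_area),
                 asym_f_c = asym_f_c, dt_s = dt_s, V_L_ml = V_L_ml),
            class = "scenario")
}

#' Read / write a scenario as YAML
#'
#' Keys carry explicit unit suffixes (`D_cm2_per_s`, `T_s`, ...) so a
#' config file cannot silently change units.  JSON files are accepted too.
#'
#' @param path Config file (`.yaml`/`.yml` or `.json`).
#' @param scn Scenario to write.
#' @return `read_scenario` returns a validated `scenario`.
#' @export
read_scenario <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  known <- names(formals(scenario))
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop("unknown scenario fields: ", paste(extra, collapse = ", "))
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  do.call(scenario, cfg)
}

#' @rdname read_scenario
#' @export
write_scenario <- function(scn, path) {
  stopifnot(inherits(scn, "scenario"))
  yaml::write_yaml(unclass(scn), path)
  invisible(path)
}

#' Build the model and transport system a scenario describes
#'
#' @param scn A `scenario`.
#' @return A `transport_system` (the model is in `$model`).
#' @export
scenario_system <- function(scn) {
  stopifnot(inherits(scn, "scenario"))
  asym <- if (!is.na(scn$asym_area) && scn$asym_f_c != 1)
    asymmetry_spec(scn$asym_area, scn$asym_f_c) else NULL
  model <- lung_model(
    V_L = scn$V_L_ml, asymmetry = asym,
    gas = gas("He-N2", scn$D_cm2_per_s),
    pattern = breathing_pattern(scn$T_s, scn$Q_cm3_per_s, scn$duration_s))
  assemble(model)
}

#' Run one scenario and write its artifacts
#'
#' Deterministic end-to-end run: builds the model, simulates the washout,
#' derives the per-breath report and writes `model.json`,
#' `table1_report.csv` (symmetric geometry regression), `mouth.csv`,
#' `breaths.csv`, `summary.json` and `run.log` (one structured line per
#' breath with end-tidal carrier fraction and the mass-balance residual)
#' into `out_dir`.
#'
#' @param scn A `scenario` object or the path of a YAML/JSON config file.
#' @param out_dir Output directory (created if missing).
#' @return The `washout_report`, invisibly; artifact paths in
#'   `attr(, "paths")`.
#' @export
run_scenario <- function(scn, out_dir) {
  if (is.character(scn)) scn <- read_scenario(scn)
  stopifnot(inherits(scn, "scenario"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  system <- scenario_system(scn)
  model <- system$model

  part_area <- if (!is.na(scn$asym_area)) scn$asym_area else NA_integer_
  part <- if (!is.na(part_area)) partition_lung_units(model, part_area)
  snaps <- if (!is.null(part))
    lu_sample_times(part, scn$T_s, scn$duration_s) else numeric(0)
  result <- simulate_washout(system, dt = scn$dt_s, snapshot_times = snaps)
  report <- washout_report(result, part)

  paths <- c(model = file.path(out_dir, "model.json"),
             table1 = file.path(out_dir, "table1_report.csv"),
             mouth = file.path(out_dir, "mouth.csv"),
             breaths = file.path(out_dir, "breaths.csv"),
             summary = file.path(out_dir, "summary.json"),
             log = file.path(out_dir, "run.log"))
  export_model_json(model, paths[["model"]])
  reproduce_table1(if (is.null(model$asymmetry)) model else NULL,
                   path = paths[["table1"]])
  write_mouth_csv(result, paths[["mouth"]])
  write_report_csv(report, paths[["breaths"]])

  residual <- abs(result$mass - result$mass[1] - result$boundary)
  breath_end <- round(seq_len(nrow(report)) * scn$T_s / result$dt) + 1L
  log_lines <- sprintf(
    "breath=%d end_tidal_N2=%.6f mass_residual=%.3e",
    report$n, report$end_tidal_N2, residual[breath_end])
  writeLines(c(sprintf("scenario=%s dt=%g scheme=%s", scn$name, scn$dt_s,
                       result$scheme), log_lines), paths[["log"]])

  peak <- s3_peak_breath(report$S3)
  plateau <- mean(report$S3_norm[pmin(15, nrow(report)):pmin(20, nrow(report))])
  summary <- list(
    scenario = unclass(scn),
    V_total_ml = lung_volumes(model)$V_total,
    V_dead_ml = lung_volumes(model)$V_dead,
    peak_breath = peak,
    peak_S3_per_L = report$S3[peak],
    S3_norm_plateau_per_L = plateau,
    max_mass_residual_ml = max(residual))
  jsonlite::write_json(summary, paths[["summary"]], auto_unbox = TRUE,
                       digits = NA, null = "null")
  attr(report, "paths") <- paths
  attr(report, "result") <- result
  invisible(report)
}

#' The standard asymmetry study grid
#'
#' The symmetric reference plus every combination of the asymmetry factors
#' 1.25, 1.50, 1.75 with areas 1-5 (factor 1.0 duplicates the symmetric
#' model and is not repeated).
#'
#' @param duration_s Simulated time per run.
#' @param dt_s Solver step.
#' @return A named list of `scenario` objects (16 entries).
#' @export
paper_grid <- function(duration_s = 200, dt_s = 5e-4) {
  grid <- list(symmetric = scenario("symmetric", duration_s = duration_s,
                                    dt_s = dt_s))
  for (f in c(1.25, 1.5, 1.75)) {
    for (a in 1:5) {
      nm <- sprintf("area%d_f%s", a, format(f))
      grid[[nm]] <- scenario(nm, asym_area = a, asym_f_c = f,
                             duration_s = duration_s, dt_s = dt_s)
    }
  }
  grid
}

#' Run the whole study grid
#'
#' @param out_dir Parent output directory; each scenario writes into its
#'   own subdirectory.
#' @param grid Scenario list, see [paper_grid()].
#' @return Named list of `washout_report`s, invisibly.
#' @export
run_grid <- function(out_dir, grid = paper_grid()) {
  reports <- lapply(names(grid), function(nm)
    run_scenario(grid[[nm]], file.path(out_dir, nm)))
  names(reports) <- names(grid)
  invisible(reports)
}
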