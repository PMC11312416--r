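#' Simulate a cohort of therapies
#'
#' Runs every therapy log through the full pipeline: build the labelled
#' domain for the configured vein, convert the log to a two-cycle balloon
#' schedule, integrate the bioheat equation, and measure the lesion.
#'
#' @param logs list of [therapy_log()] objects (or a path / data frame
#'   accepted by [read_therapy_log()]).
#' @param config a [run_config()].
#' @param keep_histories keep the full temperature histories (memory
#'   permitting); lesion estimates are always returned.
#' @param verbose print per-patient progress.
#' @return List with `estimates` (per-patient `lesion_estimate`s),
#'   `summary` (a `therapy_summary`), `domain`, and optionally
#'   `histories`.
#' @export
simulate_cohort <- function(logs, config = run_config(),
                            keep_histories = FALSE, verbose = FALSE) {
  if (!is.list(logs) || !all(vapply(logs, inherits, logical(1), "therapy_log")))
    logs <- read_therapy_log(logs)
  pieces <- config_pieces(config)
  domain <- build_domain(pieces$pv, pieces$balloon, config$resolution_mm,
                         materials = pieces$materials,
                         perfusion = pieces$perfusion,
                         wall_position = config$wall_position)
  estimates <- list(); histories <- list()
  for (log in logs) {
    if (verbose) message("patient ", log$patient_id)
    sch <- build_schedule(log, rewarm_duration = config$rewarm_duration,
                          body_temperature = config$body_temperature)
    hist <- run_therapy(domain, sch, pieces$sim, verbose = verbose)
    estimates[[log$patient_id]] <- analyze_history(
      hist, threshold_c = config$lesion_threshold_c)
    if (keep_histories) histories[[log$patient_id]] <- hist
  }
  out <- list(estimates = estimates, summary = cohort_summary(estimates),
              domain = domain)
  if (keep_histories) out$histories <- histories
  out
}

#' Write / read a lesion report
#'
#' JSON (per-patient records plus cohort statistics) and a CSV mirror of
#' the per-patient table.
#'
#' @param summary a `therapy_summary` from [cohort_summary()].
#' @param path output path; the CSV mirror replaces the extension.
#' @return `path`, invisibly.
#' @export
write_lesion_report <- function(summary, path) {
  stopifnot(inherits(summary, "therapy_summary"))
  jsonlite::write_json(list(records = summary$records, stats = summary$stats),
                       path, dataframe = "rows", digits = NA, pretty = TRUE)
  csv <- sub("\\.[^.]+$", ".csv", path)
  utils::write.csv(summary$records, csv, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_lesion_report
#' @export
read_lesion_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$records)) stop("malformed lesion report: no 'records'")
  x
}

#' Export a temperature history as long-format CSV
#'
#' Columns `time`, `r_mm`, `z_mm`, `temperature_k`.
#'
#' @param history a `cryo_history`.
#' @param path output CSV.
#' @param times snapshot times to export (default: all).
#' @return `path`, invisibly.
#' @export
export_history_csv <- function(history, path, times = NULL) {
  if (is.null(times)) times <- history$times
  cc <- cell_centers(history$domain)
  grid <- expand.grid(r_mm = cc$r_mm, z_mm = cc$z_mm)
  out <- do.call(rbind, lapply(times, function(t) {
    f <- field_at(history, t)
    data.frame(time = t, grid, temperature_k = as.vector(f))
  }))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a snapshot as a legacy VTK structured-points file
#'
#' Plain-text VTK (version 3.0) with the temperature field as point data,
#' readable by ParaView and VisIt. The axisymmetric (r, z) plane is
#' written as a 2-D structured grid.
#'
#' @param history a `cryo_history`.
#' @param path output `.vtk` path.
#' @param t snapshot time, s (default: last snapshot).
#' @return `path`, invisibly.
#' @export
export_history_vtk <- function(history, path, t = NULL) {
  if (is.null(t)) t <- max(history$times)
  f <- field_at(history, t)
  d <- history$domain
  h <- d$h * 1000
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("cryopvi temperature field at t = %g s", t),
               "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d 1", d$nr, d$nz),
               sprintf("ORIGIN %g %g 0", h / 2, h / 2),
               sprintf("SPACING %g %g 1", h, h),
               sprintf("POINT_DATA %d", d$nr * d$nz),
               "SCALARS temperature_k float 1",
               "LOOKUP_TABLE default"), con)
  writeLines(formatC(as.vector(f), format = "g", digits = 9), con)
  invisible(path)
}

#' Run a full cohort simulation and write its artifacts
#'
#' The shell-facing pipeline: read the configuration and therapy log,
#' simulate every patient, and write the lesion report (JSON + CSV), the
#' cohort summary, per-patient field exports (CSV and VTK at the end of
#' the final freeze), the configuration actually used, and a provenance
#' record. Reruns with an identical configuration produce byte-identical
#' reports.
#'
#' @param config a `run_config` or path to its YAML.
#' @param log_source therapy-log CSV path (or data frame).
#' @param out_dir output directory, created if needed.
#' @param export_fields write per-patient CSV/VTK field exports.
#' @return The `therapy_summary`, invisibly.
#' @export
cmd_simulate <- function(config, log_source, out_dir,
                         export_fields = TRUE) {
  if (is.character(config)) config <- read_run_config(config)
  logs <- read_therapy_log(log_source)   # validate before writing anything
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- simulate_cohort(logs, config, keep_histories = export_fields)
  write_lesion_report(res$summary, file.path(out_dir, "lesion_report.json"))
  utils::write.csv(res$summary$stats, file.path(out_dir, "cohort_summary.csv"),
                   row.names = FALSE, quote = FALSE)
  if (export_fields) {
    for (id in names(res$histories)) {
      h <- res$histories[[id]]
      t_eval <- res$estimates[[id]]$eval_time
      export_history_vtk(h, file.path(out_dir, sprintf("field_patient_%s.vtk", id)),
                         t = t_eval)
      export_history_csv(h, file.path(out_dir, sprintf("field_patient_%s.csv", id)),
                         times = t_eval)
    }
  }
  cfg_path <- file.path(out_dir, "config_used.yaml")
  write_run_config(config, cfg_path)
  prov <- list(package = "cryopvi",
               version = as.character(utils::packageVersion("cryopvi")),
               r_version = paste(R.version$major, R.version$minor, sep = "."),
               config_md5 = unname(tools::md5sum(cfg_path)),
               n_patients = length(logs))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res$summary)
}

#' Recompute cohort statistics from a lesion report
#'
#' @param report path to a `lesion_report.json` (or the parsed list).
#' @return A `therapy_summary` recomputed from the per-patient records.
#' @export
cmd_analyze <- function(report) {
  if (is.character(report)) report <- read_lesion_report(report)
  cohort_summary(as.data.frame(report$records))
}
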