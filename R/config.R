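#' Run configuration
#'
#' One serializable object describing a cohort simulation: vein and
#' balloon geometry, material overrides, solver controls and lesion
#' thresholds. The defaults reproduce the reference setup with no
#' overrides.
#'
#' @param vein pulmonary-vein preset name (see [pv_parameters()]).
#' @param resolution_mm cell size, mm.
#' @param timestep s.
#' @param scheme,boundary_mode see [simulation_config()].
#' @param rewarm_duration s, see [build_schedule()].
#' @param body_temperature degC.
#' @param lesion_threshold_c lesion measurement isotherm, degC.
#' @param pulmonary_layer_mm thickness of the pulmonary tissue annulus.
#' @param wall_position `"inner"` or `"outer"`, see [build_domain()].
#' @param snapshot_interval s.
#' @param latent_heat_enabled logical.
#' @param material_overrides named list of named lists, e.g.
#'   `list(blood = list(thermal_conductivity = 0.5))`.
#' @param balloon named list of [balloon_spec()] overrides.
#' @param perfusion named list of [perfusion_parameters()] overrides.
#' @return Object of class `run_config` (a validated plain list).
#' @export
run_config <- function(vein = "right inferior",
                       resolution_mm = 0.25,
                       timestep = 0.25,
                       scheme = "implicit",
                       boundary_mode = "dirichlet_schedule",
                       rewarm_duration = 30,
                       body_temperature = 36.7,
                       lesion_threshold_c = -15,
                       pulmonary_layer_mm = 10,
                       wall_position = "inner",
                       snapshot_interval = 10,
                       latent_heat_enabled = FALSE,
                       material_overrides = list(),
                       balloon = list(),
                       perfusion = list()) {
  cfg <- list(vein = vein, resolution_mm = resolution_mm,
              timestep = timestep, scheme = scheme,
              boundary_mode = boundary_mode,
              rewarm_duration = rewarm_duration,
              body_temperature = body_temperature,
              lesion_threshold_c = lesion_threshold_c,
              pulmonary_layer_mm = pulmonary_layer_mm,
              wall_position = wall_position,
              snapshot_interval = snapshot_interval,
              latent_heat_enabled = latent_heat_enabled,
              material_overrides = material_overrides,
              balloon = balloon, perfusion = perfusion)
  # validate by constructing the pieces
  invisible(config_pieces(cfg))
  structure(cfg, class = "run_config")
}

# Materialize domain-building blocks from a run_config.
#' @rdname run_config
#' @param cfg a `run_config` (or plain list with its fields).
#' @export
config_pieces <- function(cfg) {
  mats <- default_materials()
  for (m in names(cfg$material_overrides)) {
    if (!m %in% names(mats)) stop("unknown material override: ", m)
    for (f in names(cfg$material_overrides[[m]]))
      mats[[m]][[f]] <- cfg$material_overrides[[m]][[f]]
    mats[[m]] <- do.call(material_properties, unclass(mats[[m]]))
  }
  bal <- do.call(balloon_spec, cfg$balloon %||% list())
  perf <- do.call(perfusion_parameters, cfg$perfusion %||% list())
  pv <- pv_parameters(cfg$vein,
                      pulmonary_layer_thickness_mm = cfg$pulmonary_layer_mm)
  sim <- simulation_config(timestep = cfg$timestep, scheme = cfg$scheme,
                           boundary_mode = cfg$boundary_mode,
                           latent_heat_enabled = cfg$latent_heat_enabled,
                           snapshot_interval = cfg$snapshot_interval)
  list(materials = mats, balloon = bal, perfusion = perf, pv = pv, sim = sim)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  cat(yaml::as.yaml(unclass(x)))
  invisible(x)
}

#' Read / write a run configuration as YAML
#'
#' The round trip `read_run_config(write_run_config(cfg))` is the
#' identity.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  extra <- setdiff(names(raw), known)
  if (length(extra)) stop("unknown config field(s): ", paste(extra, collapse = ", "))
  do.call(run_config, raw)
}

#' @rdname read_run_config
#' @param cfg a `run_config`.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Path to a packaged example file
#'
#' @param file file name under the package's `extdata/`; with no
#'   argument, lists the available files.
#' @export
#' @examples
#' cryopvi_example()
cryopvi_example <- function(file = NULL) {
  if (is.null(file))
    return(list.files(system.file("extdata", package = "cryopvi")))
  p <- system.file("extdata", file, package = "cryopvi")
  if (!nzchar(p)) stop("no packaged file '", file, "'")
  p
}

#' Generate synthetic therapy logs
#'
#' Reproducible fixture logs spanning the observed clinical ranges:
#' TZ in [8, 13] s, TI in [23, 36] s, TM in [32, 42] s with TI < TM,
#' maximum freezing temperature in [-63, -41] degC, TT = 240 s. Every
#' generated row satisfies the therapy-log invariants.
#'
#' @param n number of logs (>= 1).
#' @param seed integer seed.
#' @return Data frame accepted by [read_therapy_log()].
#' @export
generate_fixture_logs <- function(n, seed = 1L) {
  stopifnot(n >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  TZ <- sample(8:13, n, replace = TRUE)
  TI <- sample(23:36, n, replace = TRUE)
  TM <- vapply(TI, function(ti) sample(seq(max(ti + 1, 32), 42), 1L), numeric(1))
  mx <- sample(seq(-63, -41), n, replace = TRUE)
  data.frame(patient_id = sprintf("S%03d", seq_len(n)),
             TZ = TZ, TI = TI, TM = TM, max_temperature = mx, TT = 240,
             cycles = 2L)
}
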