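# Shared fixtures and memoised simulation runs.

.run_cache <- new.env(parent = emptyenv())

table2_logs <- function() {
  read_therapy_log(cryopvi_example("table2_therapy_logs.csv"))
}

# Small, fast synthetic therapy on a reduced vein: used by property tests.
quick_log <- function(max_temp = -50, TT = 60, cycles = 1L) {
  therapy_log("q", TZ = 4, TI = 10, TM = 15, max_temperature = max_temp,
              TT = TT, cycles = cycles)
}

quick_domain <- function(resolution_mm = 0.5, perfusion = perfusion_parameters()) {
  pv <- pv_geometry("test vein", ostium_diameter = 12, wall_thickness = 1.8,
                    length_mm = 30, pulmonary_layer_thickness_mm = 4)
  build_domain(pv, balloon_spec(), resolution_mm, perfusion = perfusion)
}

quick_run <- function(max_temp = -50) {
  key <- paste0("quick", max_temp)
  if (is.null(.run_cache[[key]])) {
    cfg <- simulation_config(timestep = 0.5, snapshot_interval = 5)
    .run_cache[[key]] <- run_therapy(quick_domain(), build_schedule(
      quick_log(max_temp), rewarm_duration = 10), cfg)
  }
  .run_cache[[key]]
}

# Full default-resolution cohort runs (the study conditions): memoised so
# several tests can share them.
patient_runs <- function() {
  if (is.null(.run_cache$patients)) {
    cfg <- run_config()
    pieces <- config_pieces(cfg)
    domain <- build_domain(pieces$pv, pieces$balloon, cfg$resolution_mm)
    runs <- lapply(table2_logs(), function(log) {
      sch <- build_schedule(log, rewarm_duration = cfg$rewarm_duration)
      hist <- run_therapy(domain, sch, pieces$sim)
      list(history = hist, estimate = analyze_history(hist))
    })
    names(runs) <- vapply(table2_logs(), `[[`, character(1), "patient_id")
    .run_cache$patients <- runs
  }
  .run_cache$patients
}
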