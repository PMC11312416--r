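#' A single patient's cryotherapy log
#'
#' Thermocouple milestones of one freeze: `TZ` (s, balloon reads 0 degC),
#' `TI` (s, reads -30 degC), `TM` (s, time to isolation: maximum cold
#' reached), the maximum freezing temperature (degC) and the total
#' therapy time `TT` (s, including the return to body temperature).
#'
#' @param patient_id identifier.
#' @param TZ,TI,TM,TT times in seconds, strictly increasing, TZ > 0.
#' @param max_temperature maximum (coldest) balloon temperature, degC,
#'   at most -30.
#' @param cycles number of freeze/thaw cycles administered (default 2).
#' @return Object of class `therapy_log`.
#' @export
therapy_log <- function(patient_id, TZ, TI, TM, max_temperature, TT = 240,
                        cycles = 2L) {
  id <- as.character(patient_id)
  if (!all(is.finite(c(TZ, TI, TM, TT, max_temperature))))
    stop("patient ", id, ": all log values must be finite")
  if (!(0 < TZ && TZ < TI && TI < TM && TM < TT))
    stop("patient ", id, ": milestone times must satisfy 0 < TZ < TI < TM < TT ",
         sprintf("(got TZ=%g, TI=%g, TM=%g, TT=%g)", TZ, TI, TM, TT))
  if (max_temperature > -30)
    stop("patient ", id, ": max_temperature must be <= -30 degC (got ",
         max_temperature, ")")
  if (cycles < 1) stop("cycles must be >= 1")
  structure(list(patient_id = id, TZ = TZ, TI = TI, TM = TM,
                 max_temperature = max_temperature, TT = TT,
                 cycles = as.integer(cycles)),
            class = "therapy_log")
}

#' @export
print.therapy_log <- function(x, ...) {
  cat(sprintf("<therapy_log> patient %s: TZ=%gs, TI=%gs, TM=%gs, min %g degC, TT=%gs, %d cycle(s)\n",
              x$patient_id, x$TZ, x$TI, x$TM, x$max_temperature, x$TT, x$cycles))
  invisible(x)
}

#' Read therapy logs from a table
#'
#' Accepts a CSV path or a data frame with columns `patient_id`, `TZ`,
#' `TI`, `TM`, `max_temperature`, `TT` (and optionally `cycles`). Every
#' row is validated against the log invariants; violations are rejected
#' with a diagnostic naming the offending row.
#'
#' @param source file path or data frame.
#' @return List of [therapy_log()] objects, one per row.
#' @export
#' @examples
#' logs <- read_therapy_log(cryopvi_example("table2_therapy_logs.csv"))
#' logs[[1]]
read_therapy_log <- function(source) {
  df <- if (is.character(source)) {
    utils::read.csv(source, stringsAsFactors = FALSE)
  } else as.data.frame(source)
  need <- c("patient_id", "TZ", "TI", "TM", "max_temperature", "TT")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("therapy log table is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0L) stop("therapy log table has no rows")
  lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    tryCatch(
      therapy_log(r$patient_id, r$TZ, r$TI, r$TM, r$max_temperature, r$TT,
                  cycles = if ("cycles" %in% names(df)) r$cycles else 2L),
      error = function(e) stop("row ", i, ": ", conditionMessage(e), call. = FALSE))
  })
}

#' Write therapy logs back to CSV
#'
#' Inverse of [read_therapy_log()]; the round trip is lossless.
#'
#' @param logs list of [therapy_log()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_therapy_log <- function(logs, path) {
  df <- therapy_log_table(logs)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_therapy_log
#' @export
therapy_log_table <- function(logs) {
  do.call(rbind, lapply(logs, function(l)
    data.frame(patient_id = l$patient_id, TZ = l$TZ, TI = l$TI, TM = l$TM,
               max_temperature = l$max_temperature, TT = l$TT,
               cycles = l$cycles)))
}

#' Build the balloon surface-temperature schedule from a therapy log
#'
#' Turns the thermocouple milestones into the piecewise-linear balloon
#' surface temperature used as the moving boundary condition. Per cycle:
#' body temperature at t = 0, 0 degC at TZ, -30 degC at TI, the maximum
#' freezing temperature at TM, a hold at that minimum until
#' TT - rewarm_duration, then a linear return to body temperature at TT.
#' Cycles are concatenated end to end.
#'
#' @param log a [therapy_log()].
#' @param rewarm_duration seconds taken to return from the minimum to
#'   body temperature at the end of each cycle; must be < TT - TM.
#' @param body_temperature degC; default 36.7 (mean body temperature).
#' @return Object of class `balloon_schedule` with fields `times` (s) and
#'   `temps_c` (degC) giving the breakpoints over all cycles.
#' @export
#' @examples
#' sch <- build_schedule(therapy_log("1", 10, 23, 32, -60))
#' schedule_value(sch, c(0, 23, 32, 240))
build_schedule <- function(log, rewarm_duration = 30, body_temperature = 36.7) {
  stopifnot(inherits(log, "therapy_log"))
  if (rewarm_duration <= 0)
    stop("rewarm_duration must be positive")
  if (rewarm_duration >= log$TT - log$TM)
    stop("rewarm_duration (", rewarm_duration,
         " s) must be shorter than TT - TM = ", log$TT - log$TM, " s")
  t1 <- c(0, log$TZ, log$TI, log$TM, log$TT - rewarm_duration, log$TT)
  v1 <- c(body_temperature, 0, -30, log$max_temperature,
          log$max_temperature, body_temperature)
  times <- t1; temps <- v1
  for (cy in seq_len(log$cycles - 1L)) {
    times <- c(times, cy * log$TT + t1[-1])  # drop duplicate junction point
    temps <- c(temps, v1[-1])
  }
  structure(list(times = times, temps_c = temps, TT = log$TT,
                 cycles = log$cycles, rewarm_duration = rewarm_duration,
                 body_temperature = body_temperature, log = log),
            class = "balloon_schedule")
}

#' Evaluate a balloon schedule
#'
#' Piecewise-linear, continuous evaluation of the balloon surface
#' temperature at time `t`.
#'
#' @param schedule a `balloon_schedule`.
#' @param t time(s) in seconds, within `[0, cycles * TT]`.
#' @return Balloon surface temperature(s), degC.
#' @export
schedule_value <- function(schedule, t) {
  stopifnot(inherits(schedule, "balloon_schedule"))
  tmax <- schedule$cycles * schedule$TT
  if (any(t < 0 | t > tmax))
    stop("t must lie within [0, ", tmax, "] s")
  stats::approx(schedule$times, schedule$temps_c, xout = t,
                method = "linear", ties = "ordered")$y
}

#' @export
print.balloon_schedule <- function(x, ...) {
  cat(sprintf("<balloon_schedule> patient %s: %d cycle(s) of %g s, min %g degC, rewarm %g s\n",
              x$log$patient_id, x$cycles, x$TT, min(x$temps_c),
              x$rewarm_duration))
  invisible(x)
}

#' @export
plot.balloon_schedule <- function(x, ...) {
  tt <- seq(0, x$cycles * x$TT, length.out = 600)
  graphics::plot(tt, schedule_value(x, tt), type = "l",
                 xlab = "time (s)", ylab = "balloon surface temperature (degC)",
                 main = paste("Balloon schedule, patient", x$log$patient_id), ...)
  graphics::abline(h = c(0, -30), lty = 3, col = "grey50")
  invisible(x)
}
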