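#' Numerical controls for the bioheat integration
#'
#' @param timestep timestep, s. Backward Euler is unconditionally stable;
#'   0.25 s resolves the fastest schedule segments (~10 s ramps).
#' @param scheme `"implicit"` (backward Euler, default) or
#'   `"crank_nicolson"`.
#' @param boundary_mode `"dirichlet_schedule"` pins the balloon surface to
#'   the thermocouple-derived schedule; `"neumann_flux"` instead applies
#'   the balloon's `surface_flux_magnitude` (W/m^2) over the contact
#'   surface.
#' @param latent_heat_enabled apparent-heat-capacity phase change (off by
#'   default, matching a sensible-heat-only model).
#' @param latent_heat latent heat of fusion of tissue water, J/kg.
#' @param freeze_band_c degC interval over which the latent heat is
#'   smeared when enabled.
#' @param snapshot_interval s between stored temperature fields; must be
#'   a multiple of `timestep`.
#' @param perfusion_enabled master switch for the perfusion sink.
#' @param perfusion_frozen_cutoff_c perfusion is active only in cells
#'   warmer than this (degC); blood flow ceases in frozen tissue.
#'   Set to `-Inf` to keep perfusion on everywhere.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(timestep = 0.25,
                              scheme = c("implicit", "crank_nicolson"),
                              boundary_mode = c("dirichlet_schedule", "neumann_flux"),
                              latent_heat_enabled = FALSE,
                              latent_heat = 250e3,
                              freeze_band_c = c(-8, -1),
                              snapshot_interval = 10,
                              perfusion_enabled = TRUE,
                              perfusion_frozen_cutoff_c = 0) {
  scheme <- match.arg(scheme)
  boundary_mode <- match.arg(boundary_mode)
  stopifnot(timestep > 0, snapshot_interval > 0,
            length(freeze_band_c) == 2L, freeze_band_c[1] < freeze_band_c[2])
  structure(list(timestep = timestep, scheme = scheme,
                 boundary_mode = boundary_mode,
                 latent_heat_enabled = isTRUE(latent_heat_enabled),
                 latent_heat = latent_heat, freeze_band_c = freeze_band_c,
                 snapshot_interval = snapshot_interval,
                 perfusion_enabled = isTRUE(perfusion_enabled),
                 perfusion_frozen_cutoff_c = perfusion_frozen_cutoff_c),
            class = "simulation_config")
}

# Assemble the finite-volume operator for a domain.
# Cell-centred FV; harmonic-mean conductivity at interior faces; balloon
# and exterior Dirichlet conditions applied at the *face* with the
# adjacent cell's conductivity over a half-cell distance (ghost value).
# Returns conduction matrix over non-balloon unknowns plus face tables.
.assemble_operator <- function(domain) {
  nr <- domain$nr; nz <- domain$nz; h <- domain$h
  n <- nr * nz
  axi <- domain$geometry == "axisymmetric"
  lab <- as.vector(domain$labels)
  unknown <- lab != "balloon"
  uidx <- rep(NA_integer_, n)
  uidx[unknown] <- seq_len(sum(unknown))
  nu <- sum(unknown)
  k <- domain$k

  # face areas
  Ar <- if (axi) 2 * pi * (seq_len(nr - 1) * h) * h else rep(h, max(nr - 1, 0))
  rc <- (seq_len(nr) - 0.5) * h
  Az_byrow <- if (axi) 2 * pi * rc * h else rep(h, nr)

  # radial faces (i,j)-(i+1,j)
  fi <- rep(seq_len(nr - 1), nz); fj <- rep(seq_len(nz), each = nr - 1)
  from_r <- fi + (fj - 1L) * nr; to_r <- from_r + 1L
  area_r <- rep(Ar, nz)
  # axial faces (i,j)-(i,j+1)
  if (nz > 1) {
    gi <- rep(seq_len(nr), nz - 1); gj <- rep(seq_len(nz - 1), each = nr)
    from_z <- gi + (gj - 1L) * nr; to_z <- from_z + nr
    area_z <- rep(Az_byrow, nz - 1)
  } else {
    from_z <- to_z <- integer(0); area_z <- numeric(0)
  }
  from <- c(from_r, from_z); to <- c(to_r, to_z); area <- c(area_r, area_z)

  kh <- 2 * k[from] * k[to] / (k[from] + k[to])
  g <- kh * area / h

  u_from <- unknown[from]; u_to <- unknown[to]
  both <- u_from & u_to
  one <- xor(u_from, u_to)      # balloon boundary faces

  # conduction among unknowns
  i1 <- uidx[from[both]]; i2 <- uidx[to[both]]; gg <- g[both]
  dv <- numeric(nu)
  tab <- tapply(c(gg, gg), c(i1, i2), sum)
  dv[as.integer(names(tab))] <- tab
  C <- Matrix::sparseMatrix(i = c(i1, i2), j = c(i2, i1), x = -c(gg, gg),
                            dims = c(nu, nu)) + Matrix::Diagonal(x = dv)
  C <- Matrix::forceSymmetric(C)

  # balloon Dirichlet faces: tissue-side conductivity over half a cell
  bcell <- ifelse(unknown[from[one]], from[one], to[one])
  bball <- ifelse(unknown[from[one]], to[one], from[one])
  barea <- area[one]
  bg <- k[bcell] * barea / (h / 2)
  gb <- numeric(nu); ba <- numeric(nu)
  if (length(bcell)) {
    tb <- tapply(bg, uidx[bcell], sum)
    gb[as.integer(names(tb))] <- tb
    ta <- tapply(barea, uidx[bcell], sum)
    ba[as.integer(names(ta))] <- ta
  }

  # exterior radial edge
  ge <- numeric(nu)
  if (!is.null(domain$exterior_temperature)) {
    ecell <- nr + (seq_len(nz) - 1L) * nr
    ecell <- ecell[unknown[ecell]]
    Ae <- if (axi) 2 * pi * (nr * h) * h else h
    ge[uidx[ecell]] <- k[ecell] * Ae / (h / 2)
  }

  list(nu = nu, unknown = unknown, uidx = uidx,
       cells = which(unknown), C = C,
       gb = gb, balloon_area = ba,
       bface = list(cell = bcell, balloon = bball, g = bg, area = barea),
       ge = ge, Te = domain$exterior_temperature,
       vol = cell_volumes(domain)[unknown],
       rho = domain$rho[unknown], cp = domain$cp[unknown],
       wbcb = domain$wbcb[unknown], qm = domain$qm[unknown],
       Ta = domain$arterial_temperature)
}

.effective_rho_cp <- function(op, Tu, config) {
  rc <- op$rho * op$cp
  if (config$latent_heat_enabled) {
    band <- config$freeze_band_c + 273.15
    in_band <- Tu > band[1] & Tu < band[2]
    rc[in_band] <- rc[in_band] +
      op$rho[in_band] * config$latent_heat / diff(band)
  }
  rc
}

.perfusion_diag <- function(op, Tu, config) {
  if (!config$perfusion_enabled) return(numeric(op$nu))
  active <- Tu > config$perfusion_frozen_cutoff_c + 273.15
  op$wbcb * active
}

#' Pointwise Pennes rate of temperature change
#'
#' Evaluates the discrete right-hand side of the Pennes bioheat equation
#' \eqn{\rho c \, \partial T/\partial t = \nabla\cdot(k \nabla T) +
#' W_b C_b (T_a - T) + Q_m} for a given temperature field: the
#' finite-volume divergence of the conductive flux (harmonic-mean
#' interface conductivity) plus perfusion and metabolic terms, divided by
#' \eqn{\rho c}. Balloon cells are boundary cells and report rate 0.
#'
#' @param field temperature field, kelvin: matrix `nr x nz` or vector.
#' @param domain a `cryo_domain`.
#' @param config a [simulation_config()] (controls perfusion switching).
#' @return Matrix `nr x nz` of rates, K/s.
#' @export
pennes_rhs <- function(field, domain, config = simulation_config()) {
  Tv <- as.vector(field)
  if (length(Tv) != domain$nr * domain$nz)
    stop("field does not match the domain (", domain$nr, " x ", domain$nz, ")")
  op <- .assemble_operator(domain)
  Tu <- Tv[op$unknown]
  flux <- -as.numeric(op$C %*% Tu)                       # conduction, W
  if (length(op$bface$cell))
    flux <- flux + .accum(op$uidx[op$bface$cell],
                          op$bface$g * (Tv[op$bface$balloon] - Tv[op$bface$cell]),
                          op$nu)
  if (!is.null(op$Te))
    flux <- flux + op$ge * (op$Te - Tu)
  p <- .perfusion_diag(op, Tu, config)
  rate_u <- (flux + op$vol * (p * (op$Ta - Tu) + op$qm)) /
    (op$vol * op$rho * op$cp)
  out <- numeric(length(Tv))
  out[op$unknown] <- rate_u
  matrix(out, domain$nr, domain$nz)
}

.accum <- function(idx, x, n) {
  out <- numeric(n)
  t <- tapply(x, idx, sum)
  out[as.integer(names(t))] <- t
  out
}

#' Net conductive heat rate across the balloon surface
#'
#' Integral of the conductive flux over the balloon contact surface,
#' positive into the tissue/blood domain. Negative throughout freezing:
#' the balloon acts as a heat sink.
#'
#' @param field temperature field, kelvin (balloon cells hold the balloon
#'   surface temperature).
#' @param domain a `cryo_domain`.
#' @return Watts.
#' @export
boundary_heat_rate <- function(field, domain) {
  Tv <- as.vector(field)
  op <- .assemble_operator(domain)
  if (!length(op$bface$cell)) return(0)
  sum(op$bface$g * (Tv[op$bface$balloon] - Tv[op$bface$cell]))
}

# One theta-scheme step over the unknown cells. Perfusion switching and
# apparent heat capacity are evaluated at the previous step (lagged).
# env carries the cached Cholesky factor across steps.
.step_core <- function(op, Tv, dt, balloon_temp_c, flux_w_m2, config, env) {
  theta <- if (config$scheme == "implicit") 1 else 0.5
  Tu <- Tv[op$unknown]
  rc <- .effective_rho_cp(op, Tu, config)
  p <- .perfusion_diag(op, Tu, config)
  dirichlet <- is.null(flux_w_m2)
  gbd <- if (dirichlet) op$gb else numeric(op$nu)
  ldiag <- gbd + op$ge + op$vol * p
  Mdiag <- op$vol * rc / dt

  src <- op$vol * (p * op$Ta + op$qm)
  if (dirichlet) {
    Tb <- balloon_temp_c + 273.15
    src <- src + op$gb * Tb
  } else {
    src <- src + flux_w_m2 * op$balloon_area
  }
  if (!is.null(op$Te)) src <- src + op$ge * op$Te

  d <- Mdiag + theta * ldiag
  A <- Matrix::forceSymmetric(theta * op$C + Matrix::Diagonal(x = d))
  b <- Mdiag * Tu + src
  if (theta < 1) {
    # Crank-Nicolson: explicit half of the spatial operator; boundary and
    # source values are taken at t_new (the schedule varies slowly).
    b <- b - (1 - theta) * (as.numeric(op$C %*% Tu) + ldiag * Tu)
  }

  key <- d
  if (is.null(env$chol)) {
    env$chol <- Matrix::Cholesky(A, LDL = FALSE, super = TRUE)
    env$key <- key
  } else if (!identical(env$key, key)) {
    env$chol <- Matrix::update(env$chol, A)
    env$key <- key
  }
  Tu_new <- tryCatch(as.numeric(Matrix::solve(env$chol, b)),
                     error = function(e)
                       stop("linear solve failed (", op$nu, " unknowns, dt = ",
                            dt, " s): ", conditionMessage(e)))
  out <- Tv
  out[op$unknown] <- Tu_new
  out
}

#' Advance a temperature field by one timestep
#'
#' One implicit (or Crank-Nicolson) update of the Pennes system. In
#' Dirichlet mode the balloon-adjacent faces are pinned to the supplied
#' schedule value; in flux mode the balloon's prescribed surface flux is
#' applied instead. The exterior radial edge is held at the outer
#' material's initial temperature, the axis is a symmetry boundary, and
#' the axial ends are insulated.
#'
#' @param field temperature field, kelvin (`nr x nz` matrix or vector).
#' @param domain a `cryo_domain`.
#' @param dt timestep, s.
#' @param balloon_temp_c balloon surface temperature for this step, degC
#'   (required in Dirichlet mode).
#' @param config a [simulation_config()].
#' @return Updated `nr x nz` temperature matrix, kelvin; balloon cells are
#'   set to the balloon surface temperature for display.
#' @export
step_field <- function(field, domain, dt, balloon_temp_c = NULL,
                       config = simulation_config()) {
  stopifnot(dt > 0)
  op <- .assemble_operator(domain)
  flux <- NULL
  if (config$boundary_mode == "neumann_flux") {
    flux <- domain$balloon$surface_flux_magnitude
    if (is.null(flux)) stop("neumann_flux mode needs a balloon surface flux")
  } else if (is.null(balloon_temp_c)) {
    stop("balloon_temp_c is required in dirichlet_schedule mode")
  }
  Tv <- as.vector(field)
  env <- new.env(parent = emptyenv())
  out <- .step_core(op, Tv, dt, balloon_temp_c, flux, config, env)
  if (!is.null(balloon_temp_c)) out[!op$unknown] <- balloon_temp_c + 273.15
  matrix(out, domain$nr, domain$nz)
}

#' Integrate a full therapy
#'
#' Runs the bioheat solver from the material initial temperatures through
#' the complete (multi-cycle) balloon schedule, storing temperature
#' snapshots and per-step diagnostics.
#'
#' @param domain a `cryo_domain` from [build_domain()].
#' @param schedule a `balloon_schedule` from [build_schedule()].
#' @param config a [simulation_config()].
#' @param verbose print progress.
#' @return Object of class `cryo_history`: snapshot `times` (s), `fields`
#'   (matrix, cells by snapshots, kelvin) and a `diagnostics` data frame
#'   with per-step time, balloon temperature (degC), minimum tissue
#'   temperature (degC), balloon-boundary heat rate (W) and exterior-edge
#'   heat rate (W).
#' @export
run_therapy <- function(domain, schedule, config = simulation_config(),
                        verbose = FALSE) {
  stopifnot(inherits(domain, "cryo_domain"),
            inherits(schedule, "balloon_schedule"),
            inherits(config, "simulation_config"))
  dt <- config$timestep
  t_end <- schedule$cycles * schedule$TT
  nstep <- ceiling(t_end / dt - 1e-9)
  every <- max(1L, round(config$snapshot_interval / dt))
  op <- .assemble_operator(domain)
  flux <- if (config$boundary_mode == "neumann_flux")
    domain$balloon$surface_flux_magnitude else NULL

  lab <- as.vector(domain$labels)
  tissue <- lab %in% c("vascular_wall", "pulmonary_tissue")
  Tv <- domain$init_T
  if (is.null(flux)) Tv[!op$unknown] <- schedule_value(schedule, 0) + 273.15

  snap_t <- 0; snaps <- list(Tv)
  diag_t <- diag_bt <- diag_min <- diag_qb <- diag_qe <- numeric(nstep)
  env <- new.env(parent = emptyenv())

  for (s in seq_len(nstep)) {
    t_new <- min(s * dt, t_end)
    dts <- t_new - (s - 1) * dt
    bt <- schedule_value(schedule, t_new)
    Tv <- .step_core(op, Tv, dts, bt, flux, config, env)
    if (is.null(flux)) Tv[!op$unknown] <- bt + 273.15
    diag_t[s] <- t_new
    diag_bt[s] <- bt
    diag_min[s] <- min(Tv[tissue]) - 273.15
    Tu <- Tv[op$unknown]
    diag_qb[s] <- if (is.null(flux))
      sum(op$gb * ((bt + 273.15) - Tu)) else flux * sum(op$balloon_area)
    diag_qe[s] <- if (!is.null(op$Te)) sum(op$ge * (op$Te - Tu)) else 0
    if (s %% every == 0L || s == nstep) {
      snap_t <- c(snap_t, t_new)
      snaps[[length(snaps) + 1L]] <- Tv
    }
    if (verbose && s %% max(1L, nstep %/% 10L) == 0L)
      message(sprintf("  t = %6.1f s, balloon %7.2f degC, min tissue %7.2f degC",
                      t_new, bt, diag_min[s]))
  }
  structure(list(
    times = snap_t,
    fields = do.call(cbind, snaps),
    diagnostics = data.frame(time = diag_t, balloon_temp_c = diag_bt,
                             min_tissue_c = diag_min,
                             balloon_heat_rate_w = diag_qb,
                             exterior_heat_rate_w = diag_qe),
    domain = domain, schedule = schedule, config = config, timestep = dt
  ), class = "cryo_history")
}

#' Steady-state Pennes solution
#'
#' Direct solve of the steady discrete system (conduction + perfusion +
#' sources) under a fixed balloon surface temperature. Perfusion is taken
#' active in every perfused cell (no frozen shutoff), matching the
#' closed-form verification solutions this utility exists to check.
#'
#' @param domain a `cryo_domain`.
#' @param balloon_temp_c balloon surface temperature, degC (ignored if
#'   the domain has no balloon cells).
#' @param perfusion_enabled include the perfusion sink.
#' @return `nr x nz` temperature matrix, kelvin.
#' @export
steady_state <- function(domain, balloon_temp_c = NULL,
                         perfusion_enabled = TRUE) {
  op <- .assemble_operator(domain)
  p <- if (perfusion_enabled) op$wbcb else numeric(op$nu)
  d <- op$gb + op$ge + op$vol * p
  A <- Matrix::forceSymmetric(op$C + Matrix::Diagonal(x = d))
  src <- op$vol * (p * op$Ta + op$qm)
  if (any(op$gb > 0)) {
    if (is.null(balloon_temp_c))
      stop("balloon_temp_c required: the domain has balloon boundary faces")
    src <- src + op$gb * (balloon_temp_c + 273.15)
  }
  if (!is.null(op$Te)) src <- src + op$ge * op$Te
  Tu <- as.numeric(Matrix::solve(A, src))
  out <- numeric(domain$nr * domain$nz)
  out[op$unknown] <- Tu
  if (!is.null(balloon_temp_c)) out[!op$unknown] <- balloon_temp_c + 273.15
  matrix(out, domain$nr, domain$nz)
}

#' Closed-form 1-D steady Pennes solution
#'
#' Semi-infinite tissue at arterial temperature far away, surface held at
#' `surface_temp_c`: \eqn{T(x) = T_a + (T_s - T_a) e^{-x/\delta}} with
#' penetration depth \eqn{\delta = \sqrt{k / (W_b C_b)}} and no metabolic
#' source. Used as an independent oracle for the discrete solver.
#'
#' @param x distance from the cooled surface, m (vectorized).
#' @param surface_temp_c surface temperature, degC.
#' @param material a [material_properties()] (supplies k).
#' @param perfusion a [perfusion_parameters()] (supplies Wb, Cb, Ta).
#' @return Temperature(s), degC.
#' @export
#' @examples
#' analytic_1d_pennes(0.005, -60, default_materials()$vascular_wall)
analytic_1d_pennes <- function(x, surface_temp_c,
                               material = default_materials()$vascular_wall,
                               perfusion = perfusion_parameters()) {
  if (any(x < 0)) stop("x must be >= 0")
  wbcb <- perfusion_mass_rate(perfusion$volumetric_perfusion,
                              perfusion$blood_density) *
    perfusion$blood_specific_heat
  if (wbcb <= 0) stop("Wb * Cb must be positive for the closed form")
  delta <- sqrt(material$thermal_conductivity / wbcb)
  Ta <- perfusion$arterial_temperature - 273.15
  Ta + (surface_temp_c - Ta) * exp(-x / delta)
}

#' Total sensible enthalpy of the non-balloon cells
#'
#' \eqn{\sum_i \rho_i c_i V_i T_i} over blood and tissue cells; the
#' difference between two fields measures stored heat change, used by the
#' energy-conservation checks.
#'
#' @param field temperature field, kelvin.
#' @param domain a `cryo_domain`.
#' @return Joules (relative to 0 K).
#' @export
total_enthalpy <- function(field, domain) {
  Tv <- as.vector(field)
  unknown <- as.vector(domain$labels) != "balloon"
  sum((domain$rho * domain$cp * cell_volumes(domain) * Tv)[unknown])
}

#' @export
print.cryo_history <- function(x, ...) {
  cat(sprintf("<cryo_history> %d snapshots over %g s (%s, dt = %g s)\n",
              length(x$times), max(x$times), x$config$scheme, x$timestep))
  cat(sprintf("  minimum tissue temperature reached: %.2f degC\n",
              min(x$diagnostics$min_tissue_c)))
  invisible(x)
}

#' @export
summary.cryo_history <- function(object, ...) {
  d <- object$diagnostics
  cat("Therapy run summary\n")
  print(object$domain)
  print(object$schedule)
  cat(sprintf("  coldest tissue: %.2f degC at t = %.1f s\n",
              min(d$min_tissue_c), d$time[which.min(d$min_tissue_c)]))
  cat(sprintf("  peak balloon heat extraction: %.2f W\n",
              min(d$balloon_heat_rate_w)))
  invisible(object)
}

#' Temperature field at (or nearest to) a requested time
#'
#' @param history a `cryo_history`.
#' @param t time, s.
#' @param tol maximum allowed distance to the nearest snapshot, s.
#' @return `nr x nz` matrix, kelvin.
#' @export
field_at <- function(history, t, tol = Inf) {
  i <- which.min(abs(history$times - t))
  if (abs(history$times[i] - t) > tol)
    stop("no snapshot within ", tol, " s of t = ", t)
  matrix(history$fields[, i], history$domain$nr, history$domain$nz)
}

#' Plot a temperature snapshot
#'
#' Filled image of the (r, z) temperature field with the 0 degC and
#' -15 degC fronts overlaid.
#'
#' @param x a `cryo_history`.
#' @param t snapshot time, s (default: time of coldest tissue).
#' @param ... passed to [graphics::image()].
#' @export
plot.cryo_history <- function(x, t = NULL, ...) {
  if (is.null(t)) {
    d <- x$diagnostics
    t <- d$time[which.min(d$min_tissue_c)]
  }
  f <- field_at(x, t) - 273.15
  cc <- cell_centers(x$domain)
  graphics::image(cc$r_mm, cc$z_mm, f, col = grDevices::hcl.colors(64, "Blue-Red 2"),
                  xlab = "r (mm)", ylab = "z (mm)",
                  main = sprintf("Temperature (degC) at t = %g s", t), ...)
  graphics::contour(cc$r_mm, cc$z_mm, f, levels = c(0, -15), add = TRUE,
                    lwd = 2, col = c("darkgreen", "black"))
  invisible(x)
}
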