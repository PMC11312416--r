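test_that("perfusion mass rate converts volumetric perfusion correctly", {
  expect_equal(perfusion_mass_rate(0.012, 1057), 12.684)
  expect_equal(perfusion_mass_rate(0, 5000), 0)
  expect_equal(perfusion_mass_rate(0.012, 1000), 12)
  expect_error(perfusion_mass_rate(-0.01, 1000), "nonnegative")
})

test_that("the Pennes right-hand side vanishes at the arterial fixed point", {
  labs <- matrix("vascular_wall", 8, 6)
  d <- make_domain(labs, 0.5, geometry = "planar")
  Ta <- d$arterial_temperature
  r <- pennes_rhs(matrix(Ta, 8, 6), d)
  expect_equal(max(abs(r)), 0, tolerance = 1e-12)
})

test_that("perfusion cools a warm cell toward arterial temperature", {
  # conduction suppressed by a near-zero conductivity
  m <- list(soft = material_properties("soft", 1e-9, 3600, 1200, 310))
  d <- make_domain(matrix("soft", 3, 3), 1, materials = m, geometry = "planar")
  f <- matrix(d$arterial_temperature + 5, 3, 3)
  r <- pennes_rhs(f, d)
  expect_true(all(r < 0))
  # sign flips below Ta
  r2 <- pennes_rhs(matrix(d$arterial_temperature - 5, 3, 3), d)
  expect_true(all(r2 > 0))
})

test_that("the conduction stencil reproduces the hand-evaluated rate", {
  m <- list(custom = material_properties("custom", 1, 3600, 1200, 300))
  d <- make_domain(matrix("custom", 3, 1), 1, materials = m,
                   geometry = "planar",
                   perfusion = perfusion_parameters(volumetric_perfusion = 0))
  f <- matrix(273.15 + c(0, 1, 0), 3, 1)
  r <- pennes_rhs(f, d)
  expect_equal(r[2, 1], 1 * (0 + 0 - 2 * 1) / (1200 * 3600 * 1e-3^2),
               tolerance = 1e-12)
})

test_that("a uniform equilibrium field is a fixed point of the stepper", {
  d <- quick_domain()
  Tb <- 36.7
  # uniform field at the balloon/arterial temperature, matched exterior
  d$exterior_temperature <- Tb + 273.15
  d$arterial_temperature <- Tb + 273.15
  f0 <- matrix(Tb + 273.15, d$nr, d$nz)
  f1 <- step_field(f0, d, dt = 1, balloon_temp_c = Tb)
  expect_equal(max(abs(f1 - f0)), 0, tolerance = 1e-8)
  expect_error(step_field(f0, d, dt = 1), "balloon_temp_c")
})

test_that("the closed-form 1-D profile behaves at its limits", {
  m <- default_materials()$vascular_wall
  expect_equal(analytic_1d_pennes(0, -60, m), -60)
  expect_equal(analytic_1d_pennes(1, -60, m),
               perfusion_parameters()$arterial_temperature - 273.15,
               tolerance = 1e-6)
  # penetration depth sqrt(k / (Wb Cb)) with reference parameters
  delta <- sqrt(1.3 / (12.684 * 4000))
  expect_equal(delta * 1000, 5.0619, tolerance = 1e-4)
  expect_equal(analytic_1d_pennes(delta, -60, m),
               36.7 + (-60 - 36.7) * exp(-1), tolerance = 1e-9)
  expect_error(analytic_1d_pennes(
    0.01, -60, m, perfusion_parameters(volumetric_perfusion = 0)), "positive")
})

test_that("steady quasi-1-D solutions match the closed-form oracle", {
  h <- 0.1; nx <- 401
  labs <- matrix("vascular_wall", nx, 3)
  labs[1, ] <- "balloon"
  perf <- perfusion_parameters()
  d <- make_domain(labs, h, geometry = "planar",
                   exterior_temperature = perf$arterial_temperature)
  Ts <- -60
  f <- steady_state(d, Ts)
  xi <- (seq(2, nx) - 1.5) * h / 1000       # distance from the balloon face
  num <- f[2:nx, 2] - 273.15
  ana <- analytic_1d_pennes(xi, Ts, default_materials()$vascular_wall, perf)
  scale <- max(abs(ana - (perf$arterial_temperature - 273.15)))
  expect_lt(max(abs(num - ana)) / scale, 0.01)
})

test_that("energy is conserved when perfusion and metabolism are off", {
  pv <- pv_geometry("test vein", 12, 1.8, length_mm = 30,
                    pulmonary_layer_thickness_mm = 4)
  d <- build_domain(pv, balloon_spec(), 0.5,
                    perfusion = perfusion_parameters(volumetric_perfusion = 0))
  d$exterior_temperature <- NULL  # insulate so the balloon is the only exchange
  cfg <- simulation_config(timestep = 0.5, perfusion_enabled = FALSE,
                           snapshot_interval = 5)
  h <- run_therapy(d, build_schedule(quick_log(), rewarm_duration = 10), cfg)
  dH <- total_enthalpy(field_at(h, 60), d) - total_enthalpy(field_at(h, 0), d)
  Q <- sum(h$diagnostics$balloon_heat_rate_w * cfg$timestep)
  expect_lt(abs(dH - Q) / abs(dH), 0.005)
})

test_that("spatial convergence on a manufactured solution is second order", {
  mms_err <- function(h) {
    R <- 10; alpha <- 300
    n <- round(R / h)
    m <- list(custom = material_properties("custom", 1.3, 3600, 1200, 300))
    T_exact <- function(r_m) 273.15 + 10 * cos(alpha * r_m)
    d <- make_domain(matrix("custom", n, 3), h, materials = m,
                     perfusion = perfusion_parameters(volumetric_perfusion = 0),
                     geometry = "axisymmetric",
                     exterior_temperature = T_exact(R / 1000))
    rc <- (seq_len(n) - 0.5) * h / 1000
    # source making T_exact solve -k (1/r) d/dr(r dT/dr) = Q
    d$qm <- rep(1.3 * (10 * alpha^2 * cos(alpha * rc) +
                         10 * alpha * sin(alpha * rc) / rc), 3)
    f <- steady_state(d, perfusion_enabled = FALSE)
    max(abs(f[, 2] - T_exact(rc)))
  }
  e1 <- mms_err(0.2); e2 <- mms_err(0.1)
  expect_gte(log2(e1 / e2), 1.9)
})

test_that("identical configurations give bit-identical histories", {
  d <- quick_domain()
  cfg <- simulation_config(timestep = 0.5, snapshot_interval = 5)
  sch <- build_schedule(quick_log(), rewarm_duration = 10)
  h1 <- run_therapy(d, sch, cfg)
  h2 <- run_therapy(d, sch, cfg)
  expect_identical(h1$fields, h2$fields)
  expect_identical(h1$diagnostics, h2$diagnostics)
})

test_that("the maximum principle bounds every snapshot of a freeze", {
  h <- quick_run()
  lo <- min(h$schedule$temps_c) + 273.15
  hi <- max(c(h$domain$init_T, h$domain$exterior_temperature,
              h$domain$arterial_temperature))
  expect_true(all(h$fields >= lo - 1e-6))
  expect_true(all(h$fields <= hi + 1e-6))
})

test_that("tissue cools monotonically while the balloon freezes", {
  h <- quick_run()
  dmin <- h$diagnostics$min_tissue_c
  freeze <- h$diagnostics$time <= 60 - 10   # up to the start of rewarm
  expect_true(all(diff(dmin[freeze]) <= 1e-8))
})

test_that("the balloon boundary absorbs heat during freezing", {
  h <- quick_run()
  freeze <- h$diagnostics$time > 5 & h$diagnostics$time <= 50
  expect_true(all(h$diagnostics$balloon_heat_rate_w[freeze] < 0))
})

test_that("boundary heat rate matches Fourier's law on a steady slab", {
  m <- list(slab = material_properties("slab", 2, 1000, 1000, 300))
  nx <- 21; nzc <- 4; h <- 0.5
  labs <- matrix("slab", nx, nzc); labs[1, ] <- "balloon"
  Te <- 300
  d <- make_domain(labs, h, materials = m, geometry = "planar",
                   perfusion = perfusion_parameters(volumetric_perfusion = 0),
                   label_map = c(balloon = "slab"),
                   exterior_temperature = Te)
  f <- steady_state(d, balloon_temp_c = Te - 273.15 + 10,  # 10 K hotter face
                    perfusion_enabled = FALSE)
  q <- boundary_heat_rate(f, d)
  L <- (nx - 1) * h / 1000                  # balloon face to exterior face
  A <- nzc * h / 1000                       # unit depth
  expect_equal(q, 2 * A * 10 / L, tolerance = 1e-9)  # inflow from the hot face
  # uniform field: no flux
  expect_equal(boundary_heat_rate(matrix(300, nx, nzc), d), 0)
})

test_that("Crank-Nicolson agrees with backward Euler on a smooth problem", {
  d <- quick_domain()
  sch <- build_schedule(quick_log(), rewarm_duration = 10)
  h_be <- run_therapy(d, sch, simulation_config(timestep = 0.25,
                                                snapshot_interval = 10))
  h_cn <- run_therapy(d, sch, simulation_config(timestep = 0.25,
                                                scheme = "crank_nicolson",
                                                snapshot_interval = 10))
  f1 <- field_at(h_be, 50); f2 <- field_at(h_cn, 50)
  expect_lt(max(abs(f1 - f2)), 0.5)
})

test_that("the prescribed-flux boundary mode extracts heat", {
  d <- quick_domain()
  cfg <- simulation_config(timestep = 0.5, boundary_mode = "neumann_flux")
  f <- matrix(d$init_T, d$nr, d$nz)
  tis <- d$labels %in% c("vascular_wall", "pulmonary_tissue")
  for (i in 1:10) f <- step_field(f, d, 0.5, config = cfg)
  expect_lt(min(f[tis]), min(d$init_T[tis]))
})
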