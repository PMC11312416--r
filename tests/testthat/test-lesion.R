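test_that("temperature conversion subtracts 273.15", {
  expect_equal(kelvin_to_celsius(273.15), 0)
  expect_equal(kelvin_to_celsius(310.15), 37)
  expect_equal(kelvin_to_celsius(198.15), -75)
  expect_equal(celsius_to_kelvin(kelvin_to_celsius(311)), 311)
  expect_error(kelvin_to_celsius(-1), "nonnegative")
})

test_that("cryoinjury zones are total, contiguous and boundary-consistent", {
  expect_equal(as.character(classify_zone(-10)), "membrane_resistant")
  expect_equal(as.character(classify_zone(-18)), "extracellular_ice")
  expect_equal(as.character(classify_zone(-45)), "homogeneous_nucleation")
  expect_equal(as.character(classify_zone(20)), "above_freezing")
  # boundaries belong to the colder zone
  expect_equal(as.character(classify_zone(c(0, -15, -20, -30, -40))),
               c("membrane_resistant", "extracellular_ice", "intracellular_ice",
                 "vasoconstriction_marker", "homogeneous_nucleation"))
  # total over a fine grid, and zone index nondecreasing as T drops
  grid <- seq(50, -80, by = -0.01)
  z <- classify_zone(grid)
  expect_false(any(is.na(z)))
  expect_true(all(diff(as.integer(z)) >= 0))
  expect_error(classify_zone(NaN), "finite")
})

test_that("isotherm extraction inverts a linear radial profile", {
  d <- quick_domain(0.5)
  cc <- cell_centers(d)
  r_b <- d$lumen_radius                     # balloon contact radius, 6 mm
  # synthetic field: tissue at -30 + 10 (r - r_b) degC, everything else warm
  f <- matrix(celsius_to_kelvin(36.7), d$nr, d$nz)
  tis <- d$labels %in% c("vascular_wall", "pulmonary_tissue")
  rmat <- matrix(cc$r_mm, d$nr, d$nz)
  f[tis] <- celsius_to_kelvin(-30 + 10 * (rmat[tis] - r_b))
  front <- extract_front(f, d, -15)
  radial <- front[front[, "r_mm"] > r_b + 0.01, , drop = FALSE]
  expect_gt(nrow(radial), 0)
  expect_equal(unname(radial[, "r_mm"]), rep(r_b + 1.5, nrow(radial)),
               tolerance = 1e-9)
  # an all-body-temperature field has no front
  warm <- matrix(celsius_to_kelvin(36.7), d$nr, d$nz)
  expect_equal(nrow(extract_front(warm, d, -15)), 0)
})

test_that("colder isotherms are nested inside warmer ones", {
  h <- quick_run()
  f <- field_at(h, 50)
  s <- balloon_surface_points(h$domain$balloon, h$domain$lumen_radius,
                              h$domain$axial_center)
  depths <- vapply(c(0, -15, -20), function(th) {
    fr <- extract_front(f, h$domain, th)
    if (nrow(fr)) lesion_depth(fr, s) else 0
  }, numeric(1))
  expect_true(all(diff(depths) <= 1e-9))   # 0 degC deepest, -20 shallowest
})

test_that("lesion depth doubles the normal penetration beyond the balloon", {
  s <- balloon_surface_points(balloon_spec(), 6, 30)
  zc <- contact_band_half_height(balloon_spec(), 6)
  z_in <- seq(30 - zc + 0.2, 30 + zc - 0.2, length.out = 25)
  # front uniformly 2.14 mm beyond the contact band
  expect_equal(lesion_depth(cbind(r_mm = 6 + 2.14, z_mm = z_in), s), 4.28)
  expect_equal(lesion_depth(cbind(r_mm = 6 + 1.62, z_mm = z_in), s), 3.24)
  # front touching the surface
  expect_equal(lesion_depth(cbind(r_mm = 6, z_mm = z_in), s), 0)
  # cold channelled axially along the wall does not count
  axial <- cbind(r_mm = 6.5, z_mm = c(10, 50))
  expect_equal(lesion_depth(rbind(cbind(r_mm = 6 + 1.0, z_mm = 30), axial), s), 2)
  expect_warning(d0 <- lesion_depth(cbind(r_mm = numeric(0), z_mm = numeric(0)), s),
                 "empty front")
  expect_equal(d0, 0)
})

test_that("the elliptical area formula reproduces the reference table", {
  depths <- c(4.28, 3.24, 3.00, 3.96, 3.08)
  areas <- c(77.28, 58.50, 54.17, 71.50, 55.61)
  expect_equal(round_half_up(lesion_area(depths, 23, pi_value = 3.14), 2), areas)
  expect_true(all(abs(lesion_area(depths, 23) - areas) < 0.05))
  expect_equal(lesion_area(0, 23), 0)
  expect_equal(lesion_area(4.28, 23), pi * 2.14 * 11.5)
  expect_error(lesion_area(-1), ">= 0")
})

test_that("cohort statistics use the population standard deviation", {
  s <- pop_mean_sd(c(4.28, 3.24, 3.00, 3.96, 3.08))
  expect_equal(round(unname(s), 2), c(3.51, 0.51))
  s2 <- pop_mean_sd(c(32, 33, 42, 34, 35))
  expect_equal(round(unname(s2), 2), c(35.20, 3.54))
  # sample SD would NOT reproduce the reference dispersion
  expect_gt(round(sd(c(4.28, 3.24, 3.00, 3.96, 3.08)), 2), 0.51)
  expect_equal(unname(pop_mean_sd(7)), c(7, 0))
  expect_error(pop_mean_sd(numeric(0)), "empty")
})

test_that("lesion estimates are internally consistent and respond to cold", {
  h_cold <- quick_run(-60)
  h_warm <- quick_run(-41)
  e_cold <- analyze_history(h_cold)
  e_warm <- analyze_history(h_warm)
  # area is the ellipse of (depth, 23) by construction
  expect_equal(e_cold$area, lesion_area(e_cold$depth_A, e_cold$width_B))
  expect_equal(e_cold$width_B, 23)
  expect_equal(e_cold$distance_balloon_to_outermost_front, e_cold$depth_A / 2)
  # colder therapy freezes deeper and wider
  expect_gt(e_cold$depth_A, e_warm$depth_A)
  expect_gt(e_cold$area, e_warm$area)
  # the -15 degC lesion front sits inside the 0 degC display boundary
  expect_lte(e_cold$depth_A, e_cold$depth_0c)
})

test_that("a run that never freezes tissue yields an empty lesion", {
  d <- quick_domain()
  log <- therapy_log("warm", 4, 10, 15, max_temperature = -30, TT = 30,
                     cycles = 1L)
  sch <- build_schedule(log, rewarm_duration = 5)
  # stop the freeze almost immediately: evaluate right at the start
  h <- run_therapy(d, sch, simulation_config(timestep = 0.5,
                                             snapshot_interval = 5))
  e <- analyze_history(h, eval_time = 0)
  expect_equal(e$depth_A, 0)
  expect_equal(e$area, 0)
})

test_that("cohort summaries aggregate per-patient estimates", {
  e <- analyze_history(quick_run(-60))
  s1 <- cohort_summary(list(e))
  expect_equal(s1$stats$sd[s1$stats$metric == "depth_mm"], 0)
  df <- data.frame(depth_mm = c(4.28, 3.24, 3.00, 3.96, 3.08))
  s <- cohort_summary(df)
  expect_equal(round(s$stats$mean, 2), 3.51)
  expect_equal(round(s$stats$sd, 2), 0.51)
})
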