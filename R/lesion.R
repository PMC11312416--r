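#' Temperature conversions
#'
#' Kelvin to Celsius by subtracting 273.15 (and back).
#'
#' @param T_k temperature(s) in kelvin, nonnegative.
#' @return degC.
#' @export
#' @examples
#' kelvin_to_celsius(310.15)  # 37
kelvin_to_celsius <- function(T_k) {
  if (any(T_k < 0)) stop("kelvin temperatures must be nonnegative")
  T_k - 273.15
}

#' @rdname kelvin_to_celsius
#' @param T_c temperature(s) in degC.
#' @export
celsius_to_kelvin <- function(T_c) T_c + 273.15

.zone_levels <- c("above_freezing", "membrane_resistant", "extracellular_ice",
                  "intracellular_ice", "vasoconstriction_marker",
                  "homogeneous_nucleation")

#' Classify a temperature into a cryoinjury zone
#'
#' Zones of progressive freezing injury: above freezing; 0 to -15 degC,
#' where the cell membrane resists ice nucleation for short exposures;
#' -15 to -20 degC, extracellular ice (heterogeneous nucleation, initial
#' damage); -20 to -30 degC, intracellular ice with vascular equilibrium;
#' -30 to -40 degC, the vasoconstriction response regime; at and below
#' -40 degC, homogeneous nucleation (ice clusters inside and outside the
#' cell, irreversible death). Each boundary temperature belongs to the
#' colder zone.
#'
#' @param T_c temperature(s), degC, finite.
#' @return Factor with the zone labels.
#' @export
#' @examples
#' classify_zone(c(-10, -18, -45))
classify_zone <- function(T_c) {
  if (any(!is.finite(T_c))) stop("temperatures must be finite")
  # each boundary belongs to the colder zone
  z <- ifelse(T_c > 0, 1L,
       ifelse(T_c > -15, 2L,
       ifelse(T_c > -20, 3L,
       ifelse(T_c > -30, 4L,
       ifelse(T_c > -40, 5L, 6L)))))
  factor(.zone_levels[z], levels = .zone_levels)
}

#' Extract an isotherm front within tissue
#'
#' Linear-interpolated crossing points of the given threshold along
#' radial and axial cell lines, restricted to tissue cells (vascular wall
#' and pulmonary tissue). Where the innermost tissue cell of a ray is
#' already at or below the threshold the front is clamped to the inner
#' tissue boundary. Returns an empty set when no tissue is at or below
#' the threshold.
#'
#' @param field temperature field, kelvin (`nr x nz`).
#' @param domain the `cryo_domain` the field lives on.
#' @param threshold_c isotherm temperature, degC (default -15, the onset
#'   of extracellular ice used to measure the lesion).
#' @return Matrix with columns `r_mm`, `z_mm` (possibly 0 rows).
#' @export
extract_front <- function(field, domain, threshold_c = -15) {
  Tm <- matrix(as.vector(field), domain$nr, domain$nz) - 273.15
  tis <- matrix(domain$labels %in% c("vascular_wall", "pulmonary_tissue"),
                domain$nr, domain$nz)
  h <- domain$h * 1000
  rc <- (seq_len(domain$nr) - 0.5) * h
  zc <- (seq_len(domain$nz) - 0.5) * h
  below <- Tm <= threshold_c & tis
  if (!any(below)) return(cbind(r_mm = numeric(0), z_mm = numeric(0)))

  pts_r <- pts_z <- list()
  # radial crossings between vertically adjacent tissue cells, per column
  for (j in seq_len(domain$nz)) {
    ti <- which(tis[, j])
    if (!length(ti)) next
    # clamp at inner tissue boundary when the first tissue cell is frozen
    i0 <- ti[1]
    if (Tm[i0, j] <= threshold_c) {
      pts_r[[length(pts_r) + 1L]] <- c((i0 - 1) * h, zc[j])
    }
    run <- ti[(ti + 1L) %in% ti]           # pairs (i, i+1) both tissue
    if (length(run)) {
      T1 <- Tm[cbind(run, j)]; T2 <- Tm[cbind(run + 1L, j)]
      cross <- (T1 <= threshold_c) != (T2 <= threshold_c)
      for (i in run[cross]) {
        frac <- (threshold_c - Tm[i, j]) / (Tm[i + 1L, j] - Tm[i, j])
        pts_r[[length(pts_r) + 1L]] <- c(rc[i] + frac * h, zc[j])
      }
    }
  }
  # axial crossings between horizontally adjacent tissue cells, per row
  if (domain$nz > 1) {
    for (i in seq_len(domain$nr)) {
      tj <- which(tis[i, ])
      run <- tj[(tj + 1L) %in% tj]
      if (!length(run)) next
      T1 <- Tm[cbind(i, run)]; T2 <- Tm[cbind(i, run + 1L)]
      cross <- (T1 <= threshold_c) != (T2 <= threshold_c)
      for (j in run[cross]) {
        frac <- (threshold_c - Tm[i, j]) / (Tm[i, j + 1L] - Tm[i, j])
        pts_z[[length(pts_z) + 1L]] <- c(rc[i], zc[j] + frac * h)
      }
    }
  }
  pts <- c(pts_r, pts_z)
  if (!length(pts)) return(cbind(r_mm = numeric(0), z_mm = numeric(0)))
  out <- do.call(rbind, pts)
  colnames(out) <- c("r_mm", "z_mm")
  out
}

#' Lesion depth from a front and the balloon surface
#'
#' Doubles the maximum normal penetration of the isotherm front beyond
#' the balloon surface. For an occlusive (lumen-clipped) balloon the
#' surface normal over the contact band is radial, so penetration is the
#' radial distance beyond the band, evaluated at front points within the
#' band's axial extent; cold channelled axially along the highly
#' conductive vascular wall beyond the balloon does not register as
#' depth. For a free (unclipped) balloon the distance to the nearest
#' surface point is used wherever it is aligned with the outward surface
#' normal.
#'
#' @param front point matrix from [extract_front()].
#' @param surface balloon surface polyline from [balloon_surface_points()].
#' @param max_normal_angle_deg alignment tolerance for the free-surface
#'   case, degrees.
#' @return Depth in mm; 0 (with a warning) for an empty front.
#' @export
lesion_depth <- function(front, surface, max_normal_angle_deg = 15) {
  if (is.null(front) || nrow(front) == 0L) {
    warning("empty front: lesion depth is 0")
    return(0)
  }
  d <- .dist_to_surface(front, surface, max_normal_angle_deg)
  if (!any(is.finite(d))) return(0)
  2 * max(d[is.finite(d)])
}

# Normal penetration of each point beyond the surface polyline (-Inf for
# points excluded from the normal measure). Contact band (flat segment
# at the maximum radius, present when the balloon is clipped by the
# lumen): radial distance beyond the band for points within its axial
# extent. Otherwise: distance to the nearest sample, kept only if the
# connecting segment lies within `angle_deg` of the outward normal.
.dist_to_surface <- function(pts, surface, angle_deg = 15) {
  rmax <- max(surface[, 1])
  band <- abs(surface[, 1] - rmax) < 1e-9
  if (sum(band) >= 2L) {
    zb <- range(surface[band, 2])
    vapply(seq_len(nrow(pts)), function(i) {
      if (pts[i, 2] >= zb[1] && pts[i, 2] <= zb[2])
        max(pts[i, 1] - rmax, 0) else -Inf
    }, numeric(1))
  } else {
    # outward normals from the polyline tangent; outward = away from the
    # balloon centre (r = 0, mid z)
    tz <- c(surface[2, 2] - surface[1, 2], diff(surface[, 2]))
    tr <- c(surface[2, 1] - surface[1, 1], diff(surface[, 1]))
    nr_ <- tz; nz_ <- -tr
    ctr <- c(0, mean(range(surface[, 2])))
    flip <- nr_ * (surface[, 1] - ctr[1]) + nz_ * (surface[, 2] - ctr[2]) < 0
    nr_[flip] <- -nr_[flip]; nz_[flip] <- -nz_[flip]
    nlen <- sqrt(nr_^2 + nz_^2)
    cos_tol <- cos(angle_deg * pi / 180)
    vapply(seq_len(nrow(pts)), function(i) {
      dr <- pts[i, 1] - surface[, 1]; dz <- pts[i, 2] - surface[, 2]
      d2 <- dr^2 + dz^2
      j <- which.min(d2)
      d <- sqrt(d2[j])
      if (d < 1e-9) return(0)
      ca <- (dr[j] * nr_[j] + dz[j] * nz_[j]) / (d * nlen[j])
      if (ca < cos_tol) -Inf else d
    }, numeric(1))
  }
}

#' Elliptical lesion cross-section area
#'
#' Area of the ellipse with axes given by the lesion depth `A` and the
#' lesion width `B` (fixed at the 23 mm inflated balloon diameter):
#' \eqn{\pi (A/2) (B/2)}.
#'
#' @param depth_A lesion depth, mm (>= 0).
#' @param width_B lesion width, mm (default 23).
#' @param pi_value value of pi to use; full precision by default. Printed
#'   reference tables evaluate pi to two decimals (3.14).
#' @return Area, mm^2.
#' @export
#' @examples
#' lesion_area(4.28)                    # 77.31 full precision
#' round(lesion_area(4.28, pi_value = 3.14), 2)  # 77.28 printed convention
lesion_area <- function(depth_A, width_B = 23, pi_value = pi) {
  if (any(depth_A < 0)) stop("depth_A must be >= 0")
  if (any(width_B <= 0)) stop("width_B must be positive")
  pi_value * (depth_A / 2) * (width_B / 2)
}

#' Decimal half-up rounding
#'
#' Rounds halves away from zero in decimal arithmetic, the convention of
#' printed clinical tables (base [round()] rounds half to even on the
#' binary representation, so e.g. 54.165 prints as 54.16). A 1e-9 guard
#' absorbs binary representation error of decimal inputs.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return Rounded values.
#' @export
#' @examples
#' round_half_up(3.14 * (3.00 / 2) * (23 / 2), 2)  # 54.17
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Mean and population standard deviation
#'
#' Cohort dispersion uses the population form (divisor n), the convention
#' under which the reference per-patient tables reproduce.
#'
#' @param x numeric vector, nonempty.
#' @return Named vector `c(mean, sd)`.
#' @export
#' @examples
#' pop_mean_sd(c(4.28, 3.24, 3.00, 3.96, 3.08))  # 3.51 +/- 0.51
pop_mean_sd <- function(x) {
  if (!length(x)) stop("empty vector")
  m <- mean(x)
  c(mean = m, sd = sqrt(mean((x - m)^2)))
}

#' Lesion estimate from a completed therapy run
#'
#' Evaluates the isotherm front at the end of the final freeze phase
#' (default: end of the last hold at maximum cold, i.e.
#' `cycles * TT - rewarm_duration`), and derives lesion depth, the fixed
#' 23 mm width, the elliptical cross-section area, and two diagnostic
#' distances: the front's penetration into the vascular wall (capped at
#' the wall thickness once the cold has fully traversed it) and the
#' balloon-to-outermost-front distance (half the depth). The 0 degC
#' display boundary is reported alongside the measurement threshold.
#'
#' @param history a `cryo_history` from [run_therapy()].
#' @param threshold_c lesion measurement isotherm, degC (default -15).
#' @param eval_time evaluation time, s; `NULL` for the default above.
#' @param width_B lesion width, mm; defaults to the balloon equatorial
#'   diameter.
#' @return Object of class `lesion_estimate`.
#' @export
analyze_history <- function(history, threshold_c = -15, eval_time = NULL,
                            width_B = NULL) {
  stopifnot(inherits(history, "cryo_history"))
  dom <- history$domain
  sch <- history$schedule
  if (is.null(dom$balloon))
    stop("analyze_history needs a domain built around a balloon")
  if (is.null(eval_time))
    eval_time <- sch$cycles * sch$TT - sch$rewarm_duration
  if (is.null(width_B)) width_B <- dom$balloon$equatorial_diameter
  f <- field_at(history, eval_time, tol = history$config$snapshot_interval)
  surface <- balloon_surface_points(dom$balloon, dom$lumen_radius,
                                    dom$axial_center)
  front <- extract_front(f, dom, threshold_c)
  depth <- if (nrow(front)) lesion_depth(front, surface) else 0
  area <- lesion_area(depth, width_B)

  # penetration into (capped at through) the vascular wall -- diagnostic
  d_wall <- min(depth / 2, dom$pv$wall_thickness)
  front0 <- extract_front(f, dom, 0)
  depth0 <- if (nrow(front0)) lesion_depth(front0, surface) else 0

  structure(list(threshold = threshold_c, depth_A = depth, width_B = width_B,
                 area = area,
                 distance_balloon_to_wall = d_wall,
                 distance_balloon_to_outermost_front = depth / 2,
                 depth_0c = depth0, eval_time = eval_time,
                 patient_id = sch$log$patient_id,
                 max_temperature = sch$log$max_temperature,
                 time_to_isolation = sch$log$TM),
            class = "lesion_estimate")
}

#' @export
print.lesion_estimate <- function(x, ...) {
  cat(sprintf("<lesion_estimate> patient %s (min %g degC)\n",
              x$patient_id, x$max_temperature))
  cat(sprintf("  %g degC front at t = %g s: depth %.2f mm, width %g mm, area %.2f mm^2\n",
              x$threshold, x$eval_time, x$depth_A, x$width_B, x$area))
  cat(sprintf("  0 degC display boundary depth: %.2f mm\n", x$depth_0c))
  cat(sprintf("  front penetration into vascular wall: %.2f mm\n",
              x$distance_balloon_to_wall))
  invisible(x)
}

#' Cohort summary of per-patient lesion metrics
#'
#' Mean and population standard deviation of each metric across patients.
#'
#' @param estimates list of `lesion_estimate` objects, or a data frame
#'   with numeric metric columns.
#' @return Object of class `therapy_summary`: the per-patient table and a
#'   `stats` data frame of mean and population SD per metric.
#' @export
cohort_summary <- function(estimates) {
  df <- if (is.data.frame(estimates)) estimates else
    do.call(rbind, lapply(estimates, function(e)
      data.frame(patient_id = e$patient_id,
                 max_temperature = e$max_temperature,
                 time_to_isolation = e$time_to_isolation,
                 depth_mm = e$depth_A,
                 area_mm2 = e$area,
                 distance_balloon_to_wall = e$distance_balloon_to_wall)))
  if (nrow(df) < 1L) stop("cohort must contain at least one record")
  num <- vapply(df, is.numeric, logical(1))
  stats <- do.call(rbind, lapply(names(df)[num], function(nm) {
    s <- pop_mean_sd(df[[nm]])
    data.frame(metric = nm, mean = s[["mean"]], sd = s[["sd"]])
  }))
  structure(list(records = df, stats = stats), class = "therapy_summary")
}

#' @export
print.therapy_summary <- function(x, ...) {
  cat("<therapy_summary>", nrow(x$records), "patient(s)\n")
  for (i in seq_len(nrow(x$stats)))
    cat(sprintf("  %-28s %8.2f +/- %.2f\n", x$stats$metric[i],
                x$stats$mean[i], x$stats$sd[i]))
  invisible(x)
}
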