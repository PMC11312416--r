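#' Construct a labelled computational domain from raw cell labels
#'
#' Low-level constructor for the cell-centred finite-volume grid used by
#' the bioheat solver. Cell centres sit at \eqn{r_i = (i - 1/2) h},
#' \eqn{z_j = (j - 1/2) h}. Geometry is either axisymmetric (r, z; full
#' revolution, the first row adjoins the symmetry axis) or planar
#' (x, z with unit depth), the latter mainly for verification problems.
#'
#' @param labels character matrix (radial index by axial index) of region
#'   labels; each label must map to a material in `materials` via
#'   `label_map` (identity by default, except `balloon -> polyurethane`).
#' @param cell_size_mm grid spacing, mm (same in both directions).
#' @param materials named list of [material_properties()].
#' @param perfusion a [perfusion_parameters()] object.
#' @param geometry `"axisymmetric"` or `"planar"`.
#' @param exterior_temperature kelvin, applied as a fixed-temperature
#'   condition on the outer radial edge; `NULL` insulates that edge.
#' @param label_map named character vector mapping labels to material keys.
#' @param perfused_labels labels whose cells carry the perfusion sink;
#'   defaults to every non-balloon label.
#' @param metabolic_heat named numeric vector of volumetric sources
#'   (W/m^3) per label; unnamed labels get 0. The balloon is always 0.
#' @return Object of class `cryo_domain`.
#' @export
make_domain <- function(labels, cell_size_mm,
                        materials = default_materials(),
                        perfusion = perfusion_parameters(),
                        geometry = c("axisymmetric", "planar"),
                        exterior_temperature = NULL,
                        label_map = c(balloon = "polyurethane"),
                        perfused_labels = NULL,
                        metabolic_heat = NULL) {
  geometry <- match.arg(geometry)
  stopifnot(is.matrix(labels), is.character(labels), cell_size_mm > 0)
  labs <- unique(as.vector(labels))
  mat_key <- vapply(labs, function(l) {
    if (l %in% names(label_map)) unname(label_map[[l]]) else l
  }, character(1))
  missing <- setdiff(mat_key, names(materials))
  if (length(missing))
    stop("no material properties for label(s): ", paste(missing, collapse = ", "))
  if (is.null(perfused_labels))
    perfused_labels <- setdiff(labs, "balloon")

  nr <- nrow(labels); nz <- ncol(labels)
  lab_idx <- match(as.vector(labels), labs)
  key <- mat_key[lab_idx]
  prop <- function(field) vapply(materials[key], `[[`, numeric(1), field,
                                 USE.NAMES = FALSE)
  k <- prop("thermal_conductivity")
  rho <- prop("density")
  cp <- prop("specific_heat")
  init_T <- prop("initial_temperature")

  wb <- perfusion_mass_rate(perfusion$volumetric_perfusion,
                            perfusion$blood_density)
  wbcb <- ifelse(as.vector(labels) %in% perfused_labels,
                 wb * perfusion$blood_specific_heat, 0)
  qm <- rep(0, nr * nz)
  if (!is.null(metabolic_heat)) {
    for (l in names(metabolic_heat))
      qm[as.vector(labels) == l] <- metabolic_heat[[l]]
  }
  qm[as.vector(labels) == "balloon"] <- 0  # inert solid, no metabolism

  structure(list(
    nr = nr, nz = nz, h = cell_size_mm / 1000, geometry = geometry,
    labels = labels, k = k, rho = rho, cp = cp, init_T = init_T,
    wbcb = wbcb, qm = qm,
    arterial_temperature = perfusion$arterial_temperature,
    exterior_temperature = exterior_temperature,
    materials = materials, perfusion = perfusion,
    pv = NULL, balloon = NULL, lumen_radius = NULL, axial_center = NULL
  ), class = "cryo_domain")
}

#' Build the concentric-cylinder vein domain with an inserted balloon
#'
#' Rasterizes the layered vein model — lumen, vascular wall, pulmonary
#' tissue along the radius — onto an axisymmetric grid and inserts the
#' ellipsoidal balloon, clipped by the lumen cylinder so that a contact
#' band presses against the wall wherever the inflated balloon is wider
#' than the ostium.
#'
#' @param pv a [pv_geometry()] (or the result of [pv_parameters()]).
#' @param balloon a [balloon_spec()].
#' @param resolution_mm cell size, mm; must not exceed the wall thickness
#'   so the wall is resolved by at least one cell.
#' @param wall_position `"inner"` (default: lumen, wall, pulmonary tissue
#'   outward) or `"outer"` (lumen, pulmonary tissue, wall), the literal
#'   reading of the concentric-cylinder description.
#' @inheritParams make_domain
#' @return A `cryo_domain` carrying the vein/balloon geometry. Cells are
#'   labelled `blood`, `balloon`, `vascular_wall` or `pulmonary_tissue`
#'   with deterministic priority balloon > vascular_wall >
#'   pulmonary_tissue > blood at interfaces.
#' @export
#' @examples
#' d <- build_domain(pv_parameters("right inferior"), balloon_spec(), 0.5)
#' table(d$labels)
build_domain <- function(pv, balloon = balloon_spec(), resolution_mm = 0.25,
                         materials = default_materials(),
                         perfusion = perfusion_parameters(),
                         wall_position = c("inner", "outer"),
                         metabolic_heat = NULL) {
  wall_position <- match.arg(wall_position)
  stopifnot(inherits(pv, "pv_geometry"), inherits(balloon, "balloon_spec"))
  if (resolution_mm <= 0) stop("resolution_mm must be positive")
  if (resolution_mm > pv$wall_thickness)
    stop("resolution ", resolution_mm, " mm is coarser than the ",
         pv$wall_thickness, " mm vascular wall; the wall must be resolved")

  r_lumen <- pv$ostium_diameter / 2
  r_wall <- r_lumen + pv$wall_thickness
  r_max <- r_wall + pv$pulmonary_layer_thickness
  h <- resolution_mm
  nr <- ceiling(r_max / h)
  nz <- ceiling(pv$length / h)
  rc <- (seq_len(nr) - 0.5) * h
  zc <- (seq_len(nz) - 0.5) * h
  z0 <- if (is.null(balloon$axial_center)) pv$length / 2 else balloon$axial_center

  labels <- matrix("blood", nr, nz)
  if (wall_position == "inner") {
    labels[rc > r_lumen & rc <= r_wall, ] <- "vascular_wall"
    labels[rc > r_wall, ] <- "pulmonary_tissue"
  } else {
    r_pul <- r_lumen + pv$pulmonary_layer_thickness
    labels[rc > r_lumen & rc <= r_pul, ] <- "pulmonary_tissue"
    labels[rc > r_pul, ] <- "vascular_wall"
  }
  a <- balloon$equatorial_diameter / 2
  b <- balloon$polar_height / 2
  inside <- outer(rc, zc, function(r, z)
    (r / a)^2 + ((z - z0) / b)^2 <= 1 & r <= r_lumen)
  labels[inside] <- "balloon"
  if (!any(inside)) stop("balloon region is empty at this resolution")

  outer_key <- if (wall_position == "inner") "pulmonary_tissue" else "vascular_wall"
  d <- make_domain(labels, h, materials = materials, perfusion = perfusion,
                   geometry = "axisymmetric",
                   exterior_temperature =
                     materials[[outer_key]]$initial_temperature,
                   metabolic_heat = metabolic_heat)
  d$pv <- pv; d$balloon <- balloon
  d$lumen_radius <- r_lumen; d$axial_center <- z0
  d
}

#' @export
print.cryo_domain <- function(x, ...) {
  cat(sprintf("<cryo_domain> %s, %d x %d cells at %g mm\n",
              x$geometry, x$nr, x$nz, x$h * 1000))
  tab <- table(x$labels)
  cat("  regions:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  if (!is.null(x$pv))
    cat(sprintf("  vein: %s, lumen radius %g mm, balloon centred at z = %g mm\n",
                x$pv$name, x$lumen_radius, x$axial_center))
  invisible(x)
}

#' Cell-centre coordinates
#'
#' @param domain a `cryo_domain`.
#' @return List with vectors `r_mm`, `z_mm` of cell-centre coordinates.
#' @export
cell_centers <- function(domain) {
  h <- domain$h * 1000
  list(r_mm = (seq_len(domain$nr) - 0.5) * h,
       z_mm = (seq_len(domain$nz) - 0.5) * h)
}

#' Cell volumes
#'
#' Axisymmetric cells are full rings of volume \eqn{2 \pi r_i h^2};
#' planar cells have unit depth, volume \eqn{h^2}.
#'
#' @param domain a `cryo_domain`.
#' @return Numeric vector (column-major over the label matrix), m^3.
#' @export
cell_volumes <- function(domain) {
  h <- domain$h
  if (domain$geometry == "axisymmetric") {
    r <- (seq_len(domain$nr) - 0.5) * h
    rep(2 * pi * r * h * h, domain$nz)
  } else {
    rep(h * h, domain$nr * domain$nz)
  }
}

#' Material and perfusion parameters at a cell
#'
#' @param domain a `cryo_domain`.
#' @param i radial cell index (or linear index if `j` is missing).
#' @param j axial cell index.
#' @return List with the cell `label`, its [material_properties()], the
#'   perfusion coefficient `wbcb` (W m^-3 K^-1, 0 where unperfused), the
#'   arterial temperature and the metabolic source `qm` (W/m^3).
#' @export
material_at <- function(domain, i, j = NULL) {
  idx <- if (is.null(j)) i else i + (j - 1L) * domain$nr
  if (length(idx) != 1L || is.na(idx) || idx < 1L || idx > domain$nr * domain$nz)
    stop("cell index out of range")
  lab <- as.vector(domain$labels)[idx]
  key <- if (lab == "balloon") "polyurethane" else lab
  list(label = lab,
       material = domain$materials[[key]],
       wbcb = domain$wbcb[idx],
       arterial_temperature = domain$arterial_temperature,
       qm = domain$qm[idx])
}

#' Analytic volume of the lumen-clipped balloon
#'
#' Volume of the ellipsoid of revolution (semi-axes a radial, b axial)
#' clipped by the cylinder r <= r_lumen: a cylinder over the contact band
#' plus two ellipsoidal caps.
#'
#' @param balloon a [balloon_spec()].
#' @param lumen_radius_mm mm.
#' @return Volume in mm^3.
#' @export
clipped_balloon_volume <- function(balloon, lumen_radius_mm) {
  a <- balloon$equatorial_diameter / 2
  b <- balloon$polar_height / 2
  rl <- min(lumen_radius_mm, a)
  zc <- contact_band_half_height(balloon, lumen_radius_mm)
  cyl <- pi * rl^2 * 2 * zc
  cap <- pi * a^2 * ((b - zc) - (b^3 - zc^3) / (3 * b^2))
  cyl + 2 * cap
}

#' Points sampled along the (clipped) balloon surface
#'
#' Polyline of the balloon surface in the (r, z) half-plane: the ellipse
#' arc where it lies inside the lumen plus the straight contact segment at
#' the lumen radius. Used for normal-distance computations.
#'
#' @param balloon a [balloon_spec()].
#' @param lumen_radius_mm lumen radius, mm.
#' @param axial_center_mm balloon centre along the axis, mm.
#' @param n number of sample points.
#' @return Matrix with columns `r_mm`, `z_mm`.
#' @export
balloon_surface_points <- function(balloon, lumen_radius_mm, axial_center_mm,
                                   n = 2000L) {
  a <- balloon$equatorial_diameter / 2
  b <- balloon$polar_height / 2
  zc <- contact_band_half_height(balloon, lumen_radius_mm)
  rl <- min(lumen_radius_mm, a)
  # parametrize z from -b to b; radius = min(ellipse radius, lumen radius)
  z <- seq(-b, b, length.out = n)
  r <- a * sqrt(pmax(0, 1 - (z / b)^2))
  r <- pmin(r, rl)
  cbind(r_mm = r, z_mm = z + axial_center_mm)
}
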