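#' Material properties for a simulation region
#'
#' Bundles the thermal coefficients of one material region: thermal
#' conductivity \eqn{k} (W m\eqn{^{-1}} K\eqn{^{-1}}), specific heat
#' \eqn{c} (J kg\eqn{^{-1}} K\eqn{^{-1}}), density \eqn{\rho}
#' (kg m\eqn{^{-3}}) and the initial (reference) temperature in kelvin.
#'
#' @param name material label.
#' @param thermal_conductivity W/(m K), strictly positive.
#' @param specific_heat J/(kg K), strictly positive.
#' @param density kg/m^3, strictly positive.
#' @param initial_temperature kelvin, within [150, 320].
#' @return An object of class `material_properties`.
#' @export
material_properties <- function(name, thermal_conductivity, specific_heat,
                                density, initial_temperature) {
  stopifnot(is.character(name), length(name) == 1L)
  vals <- c(thermal_conductivity = thermal_conductivity,
            specific_heat = specific_heat,
            density = density,
            initial_temperature = initial_temperature)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("material '", name, "': all properties must be finite and positive")
  if (initial_temperature < 150 || initial_temperature > 320)
    stop("material '", name, "': initial_temperature ", initial_temperature,
         " K outside the physical range [150, 320] K")
  structure(list(name = name,
                 thermal_conductivity = thermal_conductivity,
                 specific_heat = specific_heat,
                 density = density,
                 initial_temperature = initial_temperature),
            class = "material_properties")
}

#' @export
print.material_properties <- function(x, ...) {
  cat(sprintf("<material> %s: k = %g W/(m K), c = %g J/(kg K), rho = %g kg/m^3, T0 = %g K\n",
              x$name, x$thermal_conductivity, x$specific_heat, x$density,
              x$initial_temperature))
  invisible(x)
}

#' Default material library
#'
#' The four materials of the concentric-cylinder vein model: blood in the
#' lumen, the polyurethane balloon, the vascular wall, and the surrounding
#' pulmonary tissue, each with its thermal conductivity, specific heat,
#' density and initial temperature.
#'
#' @return Named list of [material_properties()] objects with keys
#'   `blood`, `polyurethane`, `vascular_wall`, `pulmonary_tissue`.
#' @export
#' @examples
#' default_materials()$blood
default_materials <- function() {
  list(
    blood = material_properties("blood", 0.54, 4000, 1057, 310.15),
    polyurethane = material_properties("polyurethane", 0.02, 1500, 1110, 198.15),
    vascular_wall = material_properties("vascular_wall", 1.3, 3600, 1200, 310),
    pulmonary_tissue = material_properties("pulmonary_tissue", 0.03, 2963, 1000, 311)
  )
}

#' Perfusion and metabolic parameters of the Pennes sink term
#'
#' The perfusion heat sink is \eqn{W_b C_b (T_a - T)} with
#' \eqn{W_b = \omega \rho_b} the blood mass perfusion rate
#' (kg m\eqn{^{-3}} s\eqn{^{-1}}), \eqn{C_b} the blood specific heat and
#' \eqn{T_a} the arterial temperature; \eqn{Q_m} is the metabolic source.
#'
#' @param volumetric_perfusion volumetric perfusion rate in s^-1 (numerically
#'   equal to mL s^-1 cm^-3 since mL/cm^3 is dimensionless). Default 0.012.
#' @param blood_density kg/m^3.
#' @param blood_specific_heat J/(kg K).
#' @param arterial_temperature kelvin. Default 309.85 K (36.7 degC mean
#'   body temperature).
#' @param metabolic_heat W/m^3. Default 0; always 0 in the balloon, which
#'   is inert polyurethane.
#' @return Object of class `perfusion_parameters`.
#' @export
perfusion_parameters <- function(volumetric_perfusion = 0.012,
                                 blood_density = 1057,
                                 blood_specific_heat = 4000,
                                 arterial_temperature = 309.85,
                                 metabolic_heat = 0) {
  if (volumetric_perfusion < 0) stop("volumetric_perfusion must be >= 0")
  if (blood_density < 0) stop("blood_density must be >= 0")
  structure(list(volumetric_perfusion = volumetric_perfusion,
                 blood_density = blood_density,
                 blood_specific_heat = blood_specific_heat,
                 arterial_temperature = arterial_temperature,
                 metabolic_heat = metabolic_heat),
            class = "perfusion_parameters")
}

#' Blood mass perfusion rate
#'
#' Converts a volumetric perfusion rate (mL of blood per second per cm^3 of
#' tissue, i.e. s^-1 after the volume units cancel) to the mass rate
#' \eqn{W_b} entering the Pennes sink term.
#'
#' @param volumetric_perfusion s^-1 (equivalently mL s^-1 cm^-3).
#' @param blood_density kg/m^3.
#' @return kg m^-3 s^-1.
#' @export
#' @examples
#' perfusion_mass_rate(0.012, 1057)  # 12.684
perfusion_mass_rate <- function(volumetric_perfusion, blood_density) {
  if (any(volumetric_perfusion < 0) || any(blood_density < 0))
    stop("perfusion inputs must be nonnegative")
  volumetric_perfusion * blood_density
}

.pv_presets <- list(
  "right superior" = list(ostium_diameter = 18, wall_thickness = 2.7),
  "right inferior" = list(ostium_diameter = 12, wall_thickness = 1.8),
  "left superior"  = list(ostium_diameter = 19, wall_thickness = 2.8),
  "left inferior"  = list(ostium_diameter = 13, wall_thickness = 1.9)
)

#' Pulmonary-vein geometry presets
#'
#' Ostium diameter and vascular wall thickness for the four pulmonary
#' veins, plus the modelled vein length and the thickness of the
#' surrounding pulmonary-tissue layer.
#'
#' @param name one of `"right superior"`, `"right inferior"`,
#'   `"left superior"`, `"left inferior"`.
#' @param length_mm vein length along the axis, mm.
#' @param pulmonary_layer_thickness_mm thickness of the pulmonary-tissue
#'   annulus outside the vascular wall, mm. The default 10 mm is large
#'   enough to contain the -15 degC front for every therapy considered.
#' @return Object of class `pv_geometry`.
#' @export
#' @examples
#' pv_parameters("right inferior")
pv_parameters <- function(name, length_mm = 60,
                          pulmonary_layer_thickness_mm = 10) {
  if (!is.character(name) || length(name) != 1L || !name %in% names(.pv_presets))
    stop("unknown pulmonary vein '", name, "'; valid labels: ",
         paste(sQuote(names(.pv_presets)), collapse = ", "))
  p <- .pv_presets[[name]]
  pv_geometry(name, p$ostium_diameter, p$wall_thickness, length_mm,
              pulmonary_layer_thickness_mm)
}

#' @rdname pv_parameters
#' @param ostium_diameter mm, > 0.
#' @param wall_thickness mm, > 0.
#' @export
pv_geometry <- function(name, ostium_diameter, wall_thickness,
                        length_mm = 60, pulmonary_layer_thickness_mm = 10) {
  stopifnot(ostium_diameter > 0, wall_thickness > 0, length_mm > 0,
            pulmonary_layer_thickness_mm > 0)
  structure(list(name = name,
                 ostium_diameter = ostium_diameter,
                 wall_thickness = wall_thickness,
                 length = length_mm,
                 pulmonary_layer_thickness = pulmonary_layer_thickness_mm),
            class = "pv_geometry")
}

#' @export
print.pv_geometry <- function(x, ...) {
  cat(sprintf("<pulmonary vein> %s: ostium %g mm, wall %g mm, length %g mm, pulmonary layer %g mm\n",
              x$name, x$ostium_diameter, x$wall_thickness, x$length,
              x$pulmonary_layer_thickness))
  invisible(x)
}

#' Cryoballoon specification
#'
#' An inflated second-generation cryoballoon modelled as an ellipsoid of
#' revolution: 23 mm equatorial diameter, 20 mm polar height, centred on
#' the vein axis. In veins narrower than the balloon the ellipsoid is
#' clipped by the lumen so that a band of the balloon surface presses
#' directly against the vascular wall (occlusive positioning).
#'
#' @param equatorial_diameter mm (default 23).
#' @param polar_height mm (default 20).
#' @param axial_center_mm centre position along the vein axis, mm; `NULL`
#'   places the balloon at mid-length when a domain is built.
#' @param minimal_internal_temperature degC; must be <= -30.
#' @param surface_flux_magnitude prescribed surface heat-flux magnitude
#'   used by the flux boundary mode, interpreted as W/m^2 (negative =
#'   heat extracted from the tissue).
#' @return Object of class `balloon_spec`.
#' @export
balloon_spec <- function(equatorial_diameter = 23, polar_height = 20,
                         axial_center_mm = NULL,
                         minimal_internal_temperature = -80,
                         surface_flux_magnitude = -151924.04) {
  stopifnot(equatorial_diameter > 0, polar_height > 0)
  if (minimal_internal_temperature > -30)
    stop("minimal_internal_temperature must be <= -30 degC")
  structure(list(equatorial_diameter = equatorial_diameter,
                 polar_height = polar_height,
                 axial_center = axial_center_mm,
                 minimal_internal_temperature = minimal_internal_temperature,
                 surface_flux_magnitude = surface_flux_magnitude),
            class = "balloon_spec")
}

#' @export
print.balloon_spec <- function(x, ...) {
  cat(sprintf("<cryoballoon> %g x %g mm ellipsoid, internal T >= %g degC\n",
              x$equatorial_diameter, x$polar_height,
              x$minimal_internal_temperature))
  invisible(x)
}

#' Half-height of the balloon-wall contact band
#'
#' Where the balloon's equatorial radius exceeds the lumen radius the
#' ellipsoid is clipped by the lumen cylinder; contact extends axially to
#' the height where the ellipsoid radius equals the lumen radius:
#' \eqn{z = b \sqrt{1 - (r_l/a)^2}} with semi-axes \eqn{a} (radial) and
#' \eqn{b} (axial).
#'
#' @param balloon a [balloon_spec()].
#' @param lumen_radius_mm lumen radius, mm.
#' @return Half-height in mm (0 if the balloon does not reach the wall).
#' @export
contact_band_half_height <- function(balloon, lumen_radius_mm) {
  a <- balloon$equatorial_diameter / 2
  b <- balloon$polar_height / 2
  if (lumen_radius_mm >= a) return(0)
  b * sqrt(1 - (lumen_radius_mm / a)^2)
}
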