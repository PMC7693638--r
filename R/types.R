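#' Physical property and geometry containers
#'
#' Constructors validate their inputs once so downstream formulas can assume
#' well-formed values. All constructors take SI units (m, Pa.s, kg/m^3);
#' config-file readers convert from mm (see [read_chip_config()]).
#'
#' @name mps-types
NULL

stop_domain <- function(field, msg) {
  stop(sprintf("invalid %s: %s", field, msg), call. = FALSE)
}

check_positive <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_domain(field, "must be a single finite value > 0")
  x
}

#' Fluid properties
#'
#' @param viscosity dynamic viscosity in Pa.s (> 0).
#' @param density mass density in kg/m^3 (> 0).
#' @return An object of class `fluid_props`.
#' @examples
#' water() # 0.001 Pa.s, 1000 kg/m^3
#' @export
fluid_props <- function(viscosity, density) {
  check_positive(viscosity, "viscosity")
  check_positive(density, "density")
  structure(list(viscosity = viscosity, density = density),
            class = "fluid_props")
}

#' @rdname fluid_props
#' @export
water <- function() fluid_props(viscosity = 1e-3, density = 1000)

#' Channel geometry of one flow channel
#'
#' A shallow rectangular channel of constant cross-section. The culture-well
#' region (axial extent `well_span`, starting `well_offset` from the inlet) is
#' where the porous membrane couples the two channels. Port access bores
#' ("vias") drilled through the chip stack are modeled as series Poiseuille
#' resistances at the inlet and outlet; set their lengths to 0 to omit them.
#'
#' @param width_b channel width at the culture well, m (> 0).
#' @param height_h channel height, m; must not exceed `width_b` (the
#'   plane-Poiseuille closure assumes a shallow channel).
#' @param length total channel length, m.
#' @param well_span axial extent of the culture-well region, m
#'   (`well_offset + well_span <= length`).
#' @param well_offset distance from inlet to the start of the well region, m.
#'   Default centers the well.
#' @param via_length_in,via_length_out depth of the inlet/outlet access bore,
#'   m (>= 0; 0 = no bore).
#' @param via_radius radius of the access bores, m.
#' @return An object of class `channel_geometry`.
#' @export
channel_geometry <- function(width_b, height_h, length, well_span,
                             well_offset = (length - well_span) / 2,
                             via_length_in = 0, via_length_out = 0,
                             via_radius = 0.5e-3) {
  check_positive(width_b, "width_b")
  check_positive(height_h, "height_h")
  check_positive(length, "length")
  check_positive(well_span, "well_span")
  if (height_h > width_b)
    stop_domain("height_h", "must be <= width_b (shallow-channel assumption)")
  if (well_offset < 0 || well_offset + well_span > length + 1e-12)
    stop_domain("well_offset", "well region must lie within the channel")
  if (via_length_in < 0 || via_length_out < 0)
    stop_domain("via_length", "must be >= 0")
  if ((via_length_in > 0 || via_length_out > 0))
    check_positive(via_radius, "via_radius")
  structure(list(width_b = width_b, height_h = height_h, length = length,
                 well_span = well_span, well_offset = well_offset,
                 via_length_in = via_length_in,
                 via_length_out = via_length_out,
                 via_radius = via_radius),
            class = "channel_geometry")
}

#' Porous membrane specification
#'
#' Parameters of the pore-array permeability model. `porosity` is the open
#' area fraction; for a track-etched membrane with pore density n (pores per
#' unit area) it equals n * pi * pore_radius^2.
#'
#' @param pore_radius pore radius, m (> 0).
#' @param thickness membrane thickness, m (> 0).
#' @param porosity open-area fraction, strictly between 0 and 1.
#' @param area wetted (coupled) membrane area, m^2 (> 0).
#' @return An object of class `membrane_spec`.
#' @export
membrane_spec <- function(pore_radius, thickness, porosity, area) {
  check_positive(pore_radius, "pore_radius")
  check_positive(thickness, "thickness")
  check_positive(area, "area")
  if (!is.numeric(porosity) || length(porosity) != 1L ||
      porosity <= 0 || porosity >= 1)
    stop_domain("porosity", "must be strictly between 0 and 1")
  structure(list(pore_radius = pore_radius, thickness = thickness,
                 porosity = porosity, area = area),
            class = "membrane_spec")
}

#' Membrane planform for strain analysis
#'
#' Semi-axes of the elliptical membrane footprint over the culture well.
#'
#' @param semi_axis_b major semi-axis (>= `semi_axis_c`), any length unit.
#' @param semi_axis_c minor semi-axis (> 0), same unit as `semi_axis_b`.
#' @return An object of class `membrane_planform`.
#' @export
membrane_planform <- function(semi_axis_b, semi_axis_c) {
  check_positive(semi_axis_b, "semi_axis_b")
  check_positive(semi_axis_c, "semi_axis_c")
  if (semi_axis_b < semi_axis_c)
    stop_domain("semi_axis_b", "must be >= semi_axis_c")
  structure(list(semi_axis_b = semi_axis_b, semi_axis_c = semi_axis_c),
            class = "membrane_planform")
}

#' Default membrane planform: half the culture-well widths (3 x 2.25 mm).
#' @export
default_planform <- function() membrane_planform(3, 2.25)

#' Inlet boundary conditions for the network solver
#'
#' Exactly one kind per channel inlet: an imposed gauge pressure or an imposed
#' volumetric flow.
#'
#' @param value imposed inlet pressure (Pa) or inlet flow (m^3/s).
#' @return A boundary condition object for [network_config()].
#' @export
inlet_pressure <- function(value) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value))
    stop_domain("inlet pressure", "must be a single finite value")
  structure(list(kind = "pressure", value = value), class = "inlet_bc")
}

#' @rdname inlet_pressure
#' @export
inlet_flow <- function(value) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value))
    stop_domain("inlet flow", "must be a single finite value")
  structure(list(kind = "flow", value = value), class = "inlet_bc")
}

#' Discretization and boundary configuration for the coupled solver
#'
#' @param apical,basal inlet boundary conditions, from [inlet_pressure()] or
#'   [inlet_flow()].
#' @param n_segments number of membrane coupling segments (>= 1).
#' @param outlet_pressure_apical,outlet_pressure_basal imposed outlet gauge
#'   pressures, Pa. Default 0 (channels drain to open reservoirs).
#' @return An object of class `network_config`.
#' @export
network_config <- function(apical, basal, n_segments = 32,
                           outlet_pressure_apical = 0,
                           outlet_pressure_basal = 0) {
  if (!inherits(apical, "inlet_bc") || !inherits(basal, "inlet_bc"))
    stop("apical and basal must be inlet_pressure() or inlet_flow() objects",
         call. = FALSE)
  if (!is.numeric(n_segments) || length(n_segments) != 1L ||
      n_segments < 1 || n_segments != round(n_segments))
    stop_domain("n_segments", "must be an integer >= 1")
  structure(list(apical = apical, basal = basal,
                 n_segments = as.integer(n_segments),
                 outlet_pressure_apical = outlet_pressure_apical,
                 outlet_pressure_basal = outlet_pressure_basal),
            class = "network_config")
}

#' @export
print.fluid_props <- function(x, ...) {
  cat(sprintf("<fluid_props> viscosity %.3g Pa.s, density %.4g kg/m^3\n",
              x$viscosity, x$density))
  invisible(x)
}

#' @export
print.channel_geometry <- function(x, ...) {
  cat(sprintf(
    "<channel_geometry> %g x %g mm section, %g mm long; well %g mm @ %g mm",
    x$width_b * 1e3, x$height_h * 1e3, x$length * 1e3,
    x$well_span * 1e3, x$well_offset * 1e3))
  if (x$via_length_in > 0 || x$via_length_out > 0)
    cat(sprintf("; vias %g/%g mm (r=%g mm)",
                x$via_length_in * 1e3, x$via_length_out * 1e3,
                x$via_radius * 1e3))
  cat("\n")
  invisible(x)
}

#' @export
print.membrane_spec <- function(x, ...) {
  cat(sprintf(
    "<membrane_spec> pore radius %.3g um, thickness %.3g um, porosity %.3g, area %.3g mm^2\n",
    x$pore_radius * 1e6, x$thickness * 1e6, x$porosity, x$area * 1e6))
  invisible(x)
}
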