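#' Hydraulic resistances by the hydraulic-electric analogy
#'
#' Pressure-driven laminar flow maps onto Ohm's law (pressure <-> voltage,
#' flow <-> current), so the chip is solvable as a resistor network. These
#' functions compute the elementary resistances.
#'
#' A single cylindrical pore of radius R and length L has Poiseuille
#' resistance R_pore = 8 mu L / (pi R^4). A track-etched membrane is a
#' parallel array of such pores: with pore density n = porosity / (pi R^2)
#' over wetted area A it carries A n pores, so
#' R_memb = R_pore / (A n) = 8 mu L / (R^2 A porosity).
#' Equivalently, Darcy flow with permeability k = porosity R^2 / 8 gives
#' Q = k A dP / (mu L), i.e. R_memb = mu L / (k A) -- the two forms agree
#' to machine precision.
#'
#' @param membrane a [membrane_spec()].
#' @param fluid a [fluid_props()].
#' @return A `hydraulic_resistance` object: value in Pa.s/m^3 plus a `scope`
#'   tag (`single_pore`, `whole_membrane`, or `channel_segment`).
#' @seealso [permeability()], [channel_resistance()]
#' @export
pore_resistance <- function(membrane, fluid) {
  stopifnot(inherits(membrane, "membrane_spec"), inherits(fluid, "fluid_props"))
  val <- 8 * fluid$viscosity * membrane$thickness / (pi * membrane$pore_radius^4)
  hydraulic_resistance(val, "single_pore")
}

#' @rdname pore_resistance
#' @export
membrane_resistance <- function(membrane, fluid) {
  stopifnot(inherits(membrane, "membrane_spec"), inherits(fluid, "fluid_props"))
  n_pore <- membrane$porosity / (pi * membrane$pore_radius^2)
  val <- pore_resistance(membrane, fluid)$value / (membrane$area * n_pore)
  hydraulic_resistance(val, "whole_membrane")
}

#' Darcy permeability of the pore-array membrane
#'
#' k = porosity * pore_radius^2 / 8, in m^2 (equivalently pi n R^4 / 8 with
#' n the pore density). Satisfies mu*thickness/(k*area) == membrane
#' resistance exactly.
#'
#' @inheritParams pore_resistance
#' @return Permeability in m^2.
#' @export
permeability <- function(membrane) {
  stopifnot(inherits(membrane, "membrane_spec"))
  membrane$porosity * membrane$pore_radius^2 / 8
}

#' Axial resistance of a shallow rectangular channel
#'
#' Plane-Poiseuille closure R = 12 mu L / (b h^3), consistent with the
#' shallow-channel wall-shear formula. `exact = TRUE` applies the leading
#' rectangular-duct correction 1/(1 - 0.63 h/b).
#'
#' @param geometry a [channel_geometry()].
#' @param fluid a [fluid_props()].
#' @param length axial length to use, m. Defaults to the full channel length.
#' @param exact use the rectangular-duct correction factor.
#' @return A `hydraulic_resistance` with scope `channel_segment`.
#' @export
channel_resistance <- function(geometry, fluid, length = geometry$length,
                               exact = FALSE) {
  stopifnot(inherits(geometry, "channel_geometry"),
            inherits(fluid, "fluid_props"))
  val <- 12 * fluid$viscosity * length /
    (geometry$width_b * geometry$height_h^3)
  if (exact) val <- val / (1 - 0.63 * geometry$height_h / geometry$width_b)
  hydraulic_resistance(val, "channel_segment")
}

#' @rdname pore_resistance
#' @param value resistance in Pa.s/m^3 (> 0).
#' @param scope one of `"single_pore"`, `"whole_membrane"`,
#'   `"channel_segment"`.
#' @export
hydraulic_resistance <- function(value, scope) {
  scope <- match.arg(scope,
                     c("single_pore", "whole_membrane", "channel_segment"))
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value) ||
      value <= 0)
    stop_domain("resistance value", "must be a single finite value > 0")
  structure(list(value = value, scope = scope), class = "hydraulic_resistance")
}

#' @export
print.hydraulic_resistance <- function(x, ...) {
  cat(sprintf("<hydraulic_resistance> %.4g Pa.s/m^3 (%s)\n", x$value, x$scope))
  invisible(x)
}

#' Poiseuille resistance of a circular bore
#'
#' Used for the port access vias of the chip stack.
#' @keywords internal
via_resistance <- function(length, radius, fluid) {
  if (length <= 0) return(0)
  8 * fluid$viscosity * length / (pi * radius^4)
}

#' Wall shear stress in a shallow rectangular channel
#'
#' tau = 6 mu Q / (b h^2), the plane-Poiseuille wall shear at the membrane
#' surface for volumetric flow Q.
#'
#' @param Q volumetric flow, m^3/s (>= 0; vectorized).
#' @param geometry a [channel_geometry()].
#' @param fluid a [fluid_props()].
#' @return Shear stress in Pa.
#' @examples
#' tau <- wall_shear_stress(ul_min_to_m3_s(100),
#'                          channel_geometry(6e-3, 0.5e-3, 35e-3, 6e-3),
#'                          water())  # ~6.7e-3 Pa
#' @export
wall_shear_stress <- function(Q, geometry, fluid) {
  stopifnot(inherits(geometry, "channel_geometry"),
            inherits(fluid, "fluid_props"))
  if (any(Q < 0)) stop("Q must be >= 0", call. = FALSE)
  6 * fluid$viscosity * Q / (geometry$width_b * geometry$height_h^2)
}
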