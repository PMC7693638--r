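#' Semi-ellipsoid surface area of a deflected membrane
#'
#' The pressurized membrane over an elliptical culture well is approximated
#' as a half-ellipsoid of cap height `a` (the measured center deflection)
#' over semi-axes b >= c, plus the base ellipse:
#' SA = 2 pi [((a b)^p + (a c)^p + (b c)^p) / 3]^(1/p) + pi b c,
#' with Thomsen exponent p = 1.6075 (exact for the sphere: a = b = c = r
#' gives 3 pi r^2). Units: any length unit, used consistently for `a` and
#' the planform; area returned in that unit squared.
#'
#' Note the a = 0 limit of the cap term is 2 pi b c (1/3)^(1/p), not the
#' flat ellipse pi b c; strain therefore always uses the same formula for
#' both the deflected and undeflected state (see [biaxial_strain()]).
#'
#' @param a center deflection (>= 0; vectorized).
#' @param planform a [membrane_planform()].
#' @return Surface area(s).
#' @export
semi_ellipsoid_area <- function(a, planform) {
  stopifnot(inherits(planform, "membrane_planform"))
  if (any(a < 0)) stop("deflection a must be >= 0", call. = FALSE)
  p <- THOMSEN_P
  b <- planform$semi_axis_b
  c_ <- planform$semi_axis_c
  cap <- 2 * pi * (((a * b)^p + (a * c_)^p + (b * c_)^p) / 3)^(1 / p)
  cap + pi * b * c_
}

THOMSEN_P <- 1.6075

#' Bi-axial surface strain from membrane deflection
#'
#' Fractional surface-area expansion eps_SA = (SA_f - SA_0)/SA_0, with both
#' areas evaluated by [semi_ellipsoid_area()] (SA_0 at a = 0), so that
#' eps_SA(0) = 0 exactly and the formula's degenerate-case bias cancels.
#' Strictly increasing in `a`.
#'
#' @inheritParams semi_ellipsoid_area
#' @return Strain value(s), dimensionless.
#' @export
biaxial_strain <- function(a, planform) {
  sa0 <- semi_ellipsoid_area(0, planform)
  (semi_ellipsoid_area(a, planform) - sa0) / sa0
}

#' Deflection at which a target bi-axial strain is reached
#'
#' Inverse of [biaxial_strain()] by root bracketing; used e.g. to locate the
#' center deflection corresponding to a 4% maximum strain.
#'
#' @param target target strain (> 0).
#' @param planform a [membrane_planform()].
#' @param upper upper bracket for the deflection, same unit as the planform.
#' @return Deflection at which `biaxial_strain()` equals `target`.
#' @export
deflection_for_strain <- function(target, planform,
                                  upper = 2 * planform$semi_axis_b) {
  stopifnot(target > 0)
  stats::uniroot(function(a) biaxial_strain(a, planform) - target,
                 lower = 0, upper = upper, tol = 1e-12)$root
}

#' Convert a pressure-deflection sweep into a strain curve
#'
#' Applies [biaxial_strain()] elementwise to a sweep of deflection records
#' (e.g. 0 to 315 mbar in 15 mbar steps), preserving pressure order.
#'
#' @param records data.frame with columns `pressure_mbar` and
#'   `deflection_mm` (deflection in the same unit as the planform; the CSV
#'   reader [read_deflection_sweep()] converts from micrometers). At least
#'   2 records, strictly increasing pressure.
#' @param planform a [membrane_planform()] in mm.
#' @return A data.frame of class `strain_curve`: `pressure_mbar`, `strain`.
#' @export
strain_sweep <- function(records, planform) {
  stopifnot(is.data.frame(records))
  need <- c("pressure_mbar", "deflection_mm")
  if (!all(need %in% names(records)))
    stop("records must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(records) < 2)
    stop("a sweep needs at least 2 records", call. = FALSE)
  if (anyDuplicated(records$pressure_mbar))
    stop("duplicate pressures in sweep", call. = FALSE)
  if (is.unsorted(records$pressure_mbar, strictly = TRUE))
    stop("sweep pressures must be strictly increasing", call. = FALSE)
  out <- data.frame(
    pressure_mbar = records$pressure_mbar,
    strain = biaxial_strain(records$deflection_mm, planform))
  class(out) <- c("strain_curve", "data.frame")
  out
}
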