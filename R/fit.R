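#' Fit a pressure-flow line and recover hydraulic resistance
#'
#' Least-squares line Q = P/R + b through applied-pressure / mean-flow pairs,
#' as measured in a flow-meter sweep. The fitted resistance is the inverse
#' slope. A flat line (zero slope within machine tolerance) has undefined
#' resistance and is flagged.
#'
#' @param pressures applied pressures (>= 3 distinct values).
#' @param flows measured mean flows, same length.
#' @param pressure_unit `"Pa"` (default) or `"mbar"`.
#' @param flow_unit `"m3_s"` (default) or `"ul_min"`.
#' @return A `pq_fit` list: `resistance` (Pa.s/m^3, `NA` if degenerate),
#'   `slope`, `intercept` (SI), `r_squared`, and `degenerate` flag.
#' @export
fit_pq_line <- function(pressures, flows, pressure_unit = c("Pa", "mbar"),
                        flow_unit = c("m3_s", "ul_min")) {
  pressure_unit <- match.arg(pressure_unit)
  flow_unit <- match.arg(flow_unit)
  if (length(pressures) != length(flows))
    stop("pressures and flows must have equal length", call. = FALSE)
  if (length(unique(pressures)) < 3)
    stop("need >= 3 distinct pressures to fit a line", call. = FALSE)
  p <- if (pressure_unit == "mbar") mbar_to_pa(pressures) else pressures
  q <- if (flow_unit == "ul_min") ul_min_to_m3_s(flows) else flows
  if (diff(range(p)) <= 0)
    stop("zero pressure spread", call. = FALSE)
  fit <- stats::lm(q ~ p)
  slope <- unname(stats::coef(fit)[2])
  scale <- max(abs(q)) / diff(range(p))
  degenerate <- !is.finite(slope) ||
    abs(slope) <= max(scale, .Machine$double.xmin) * 1e-12
  ss_tot <- sum((q - mean(q))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::resid(fit)^2) / ss_tot else NA_real_
  structure(list(
    resistance = if (degenerate) NA_real_ else 1 / slope,
    slope = slope,
    intercept = unname(stats::coef(fit)[1]),
    r_squared = r2,
    degenerate = degenerate
  ), class = "pq_fit")
}

#' @export
print.pq_fit <- function(x, ...) {
  if (x$degenerate)
    cat("<pq_fit> degenerate (flat line); resistance undefined\n")
  else
    cat(sprintf("<pq_fit> resistance %.4g Pa.s/m^3, R^2 %.5f\n",
                x$resistance, x$r_squared))
  invisible(x)
}

#' Recover membrane permeability from observed transmembrane flows
#'
#' Inverse use of the coupled network model: finds the Darcy permeability k
#' minimizing the sum of squared misfits between [solve_coupled_network()]
#' predictions and observed transmembrane flows over one or more operating
#' points. k maps onto the membrane spec through porosity = 8 k / R^2, so the
#' returned spec keeps the template's pore radius, thickness and area.
#'
#' @param observations data.frame with columns `apical_flow_ul_min`,
#'   `basal_flow_ul_min`, `q_tm_ul_min` (one row per operating point).
#' @param apical,basal,fluid chip description as in [solve_coupled_network()].
#' @param membrane_template [membrane_spec()] supplying pore radius,
#'   thickness and area; its permeability seeds the search bracket.
#' @param n_segments discretization used for the forward model.
#' @param k_bracket_factor search spans `k0 / f` .. `k0 * f` around the
#'   template permeability `k0`.
#' @return A `k_fit` list: `k` (m^2), `membrane` (spec at fitted k), `sse`,
#'   and `identifiable` flag (`FALSE` when no pressure gradient drives flow,
#'   or all observed flows are zero, in which case `k` is the lower bracket
#'   edge, i.e. effectively zero).
#' @export
fit_membrane_permeability <- function(observations, apical, basal,
                                      membrane_template, fluid,
                                      n_segments = 16,
                                      k_bracket_factor = 1e3) {
  stopifnot(is.data.frame(observations), nrow(observations) >= 1)
  need <- c("apical_flow_ul_min", "basal_flow_ul_min", "q_tm_ul_min")
  if (!all(need %in% names(observations)))
    stop("observations must have columns ",
         paste(need, collapse = ", "), call. = FALSE)

  k0 <- permeability(membrane_template)
  spec_at_k <- function(k) {
    porosity <- min(1 - 1e-12, 8 * k / membrane_template$pore_radius^2)
    membrane_spec(membrane_template$pore_radius, membrane_template$thickness,
                  porosity, membrane_template$area)
  }
  predict_qtm <- function(k) {
    vapply(seq_len(nrow(observations)), function(i) {
      cfg <- network_config(
        apical = inlet_flow(ul_min_to_m3_s(observations$apical_flow_ul_min[i])),
        basal = inlet_flow(ul_min_to_m3_s(observations$basal_flow_ul_min[i])),
        n_segments = n_segments)
      m3_s_to_ul_min(transmembrane_flow(
        solve_coupled_network(apical, basal, spec_at_k(k), fluid, cfg)))
    }, numeric(1))
  }

  # identifiability: any gradient at all at the template k?
  pred0 <- predict_qtm(k0)
  obs <- observations$q_tm_ul_min
  if (max(abs(pred0)) == 0) {
    return(structure(list(k = NA_real_, membrane = NULL, sse = NA_real_,
                          identifiable = FALSE), class = "k_fit"))
  }
  if (max(abs(obs)) == 0) {
    k_lo <- k0 / k_bracket_factor
    return(structure(list(k = k_lo, membrane = spec_at_k(k_lo),
                          sse = sum(pred0^2), identifiable = FALSE),
                     class = "k_fit"))
  }

  sse <- function(log_k) sum((predict_qtm(exp(log_k)) - obs)^2)
  opt <- stats::optimize(sse,
                         interval = log(c(k0 / k_bracket_factor,
                                          k0 * k_bracket_factor)),
                         tol = 1e-10)
  k_hat <- exp(opt$minimum)
  structure(list(k = k_hat, membrane = spec_at_k(k_hat),
                 sse = opt$objective, identifiable = TRUE),
            class = "k_fit")
}

#' @export
print.k_fit <- function(x, ...) {
  if (!x$identifiable)
    cat("<k_fit> not identifiable from these observations\n")
  else
    cat(sprintf("<k_fit> k = %.4g m^2 (sse %.3g)\n", x$k, x$sse))
  invisible(x)
}
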