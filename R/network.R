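#' Reduced-order coupled two-channel network solver
#'
#' Discretizes each flow channel into axial Poiseuille resistors and couples
#' them across the culture-well overlap through the membrane resistance,
#' apportioned over `n_segments` coupling segments. The resulting linear
#' nodal system (Kirchhoff current law at every node) is solved directly;
#' the system is tiny, so no iterative tolerance is exposed.
#'
#' Boundary conditions: each inlet carries either an imposed gauge pressure
#' or an imposed volumetric flow ([inlet_pressure()] / [inlet_flow()]); both
#' outlets are held at imposed gauge pressure (default 0 = atmospheric).
#' Port access vias declared in the [channel_geometry()] enter as series
#' resistances at the channel ends.
#'
#' Sign convention: transmembrane flux is positive basal -> apical (the
#' "urinary" direction in a glomerular-barrier configuration).
#'
#' @param apical,basal [channel_geometry()] for the two channels.
#' @param membrane a [membrane_spec()]; couples the channels only over the
#'   well region.
#' @param fluid a [fluid_props()].
#' @param config a [network_config()].
#' @param exact_duct use the rectangular-duct correction for channel
#'   resistances (see [channel_resistance()]).
#' @return A `flow_solution` object with node pressures, axial segment flows,
#'   per-segment transmembrane fluxes, inlet/outlet flows and the parameter
#'   set used.
#' @seealso [transmembrane_flow()], [conservation_residual()]
#' @export
solve_coupled_network <- function(apical, basal, membrane, fluid, config,
                                  exact_duct = FALSE) {
  stopifnot(inherits(apical, "channel_geometry"),
            inherits(basal, "channel_geometry"),
            inherits(membrane, "membrane_spec"),
            inherits(fluid, "fluid_props"),
            inherits(config, "network_config"))
  n <- config$n_segments
  r_memb <- membrane_resistance(membrane, fluid)$value

  ch_a <- channel_mesh(apical, fluid, n, exact_duct)
  ch_b <- channel_mesh(basal, fluid, n, exact_duct)
  na <- ch_a$n_nodes
  nb <- ch_b$n_nodes
  nn <- na + nb

  edges_i <- c(ch_a$edges_i, ch_b$edges_i + na)
  edges_j <- c(ch_a$edges_j, ch_b$edges_j + na)
  edges_g <- c(ch_a$edges_g, ch_b$edges_g)

  # membrane coupling: trapezoidal nodal weights over the n+1 well nodes
  w <- c(0.5, rep(1, n - 1), 0.5)[seq_len(n + 1)]
  if (n == 1) w <- c(0.5, 0.5)
  w <- w / n
  g_memb <- w / r_memb
  memb_i <- ch_a$well_nodes
  memb_j <- ch_b$well_nodes + na

  G <- matrix(0, nn, nn)
  add_edge <- function(G, i, j, g) {
    for (k in seq_along(i)) {
      G[i[k], i[k]] <- G[i[k], i[k]] + g[k]
      G[j[k], j[k]] <- G[j[k], j[k]] + g[k]
      G[i[k], j[k]] <- G[i[k], j[k]] - g[k]
      G[j[k], i[k]] <- G[j[k], i[k]] - g[k]
    }
    G
  }
  G <- add_edge(G, edges_i, edges_j, edges_g)
  G <- add_edge(G, memb_i, memb_j, g_memb)

  # boundary conditions
  source_vec <- numeric(nn)
  known <- integer(0)
  known_val <- numeric(0)
  apply_inlet <- function(bc, inlet_node, offset) {
    if (bc$kind == "pressure") {
      known <<- c(known, inlet_node + offset)
      known_val <<- c(known_val, bc$value)
    } else {
      source_vec[inlet_node + offset] <<- source_vec[inlet_node + offset] +
        bc$value
    }
  }
  apply_inlet(config$apical, ch_a$inlet_node, 0)
  apply_inlet(config$basal, ch_b$inlet_node, na)
  known <- c(known, ch_a$outlet_node, ch_b$outlet_node + na)
  known_val <- c(known_val, config$outlet_pressure_apical,
                 config$outlet_pressure_basal)

  unknown <- setdiff(seq_len(nn), known)
  p <- numeric(nn)
  p[known] <- known_val
  rhs <- source_vec[unknown] -
    G[unknown, known, drop = FALSE] %*% known_val
  p[unknown] <- tryCatch(
    drop(solve(G[unknown, unknown, drop = FALSE], rhs)),
    error = function(e) stop(
      "singular network configuration: no pressure reference reachable (",
      conditionMessage(e), ")", call. = FALSE))

  # fluxes
  flow_a <- (p[ch_a$edges_i] - p[ch_a$edges_j]) * ch_a$edges_g
  flow_b <- (p[ch_b$edges_i + na] - p[ch_b$edges_j + na]) * ch_b$edges_g
  dpn <- p[memb_j] - p[memb_i] # basal - apical at well nodes
  tm_node <- g_memb * dpn
  tm_seg <- (dpn[-(n + 1)] + dpn[-1]) / (2 * n) / r_memb

  residual <- drop(G %*% p) - source_vec
  q_in_a <- if (config$apical$kind == "flow") config$apical$value else
    residual[ch_a$inlet_node]
  q_in_b <- if (config$basal$kind == "flow") config$basal$value else
    residual[ch_b$inlet_node + na]
  q_out_a <- -residual[ch_a$outlet_node]
  q_out_b <- -residual[ch_b$outlet_node + na]

  structure(list(
    node_positions_apical = ch_a$pos,
    node_positions_basal = ch_b$pos,
    node_pressures_apical = p[seq_len(na)],
    node_pressures_basal = p[na + seq_len(nb)],
    segment_flows_apical = flow_a,
    segment_flows_basal = flow_b,
    well_nodes_apical = ch_a$well_nodes,
    well_nodes_basal = ch_b$well_nodes,
    transmembrane_flux = tm_seg,
    transmembrane_flux_nodal = tm_node,
    q_inlet_apical = q_in_a, q_outlet_apical = q_out_a,
    q_inlet_basal = q_in_b, q_outlet_basal = q_out_b,
    interior_residual = residual[setdiff(unknown, c(ch_a$inlet_node,
                                                    ch_b$inlet_node + na))],
    params = list(membrane = membrane, fluid = fluid, apical = apical,
                  basal = basal, config = config,
                  r_membrane = r_memb, permeability = permeability(membrane),
                  exact_duct = exact_duct)
  ), class = "flow_solution")
}

# Mesh one channel: well nodes 1..(n+1); separate inlet/outlet nodes only
# when the lead resistance (channel lead + via) is nonzero.
channel_mesh <- function(geom, fluid, n, exact_duct) {
  r_per_len <- channel_resistance(geom, fluid, length = 1,
                                  exact = exact_duct)$value
  lead_in <- r_per_len * geom$well_offset +
    via_resistance(geom$via_length_in, geom$via_radius, fluid)
  lead_out_len <- geom$length - geom$well_offset - geom$well_span
  lead_out <- r_per_len * lead_out_len +
    via_resistance(geom$via_length_out, geom$via_radius, fluid)

  wn <- n + 1
  pos <- geom$well_offset + geom$well_span * (0:n) / n
  well_nodes <- seq_len(wn)
  edges_i <- well_nodes[-wn]
  edges_j <- well_nodes[-1]
  edges_g <- rep(1 / (r_per_len * geom$well_span / n), n)
  n_nodes <- wn

  if (lead_in > 0) {
    n_nodes <- n_nodes + 1
    inlet_node <- n_nodes
    pos <- c(pos, 0)
    edges_i <- c(edges_i, inlet_node)
    edges_j <- c(edges_j, 1L)
    edges_g <- c(edges_g, 1 / lead_in)
  } else inlet_node <- 1L
  if (lead_out > 0) {
    n_nodes <- n_nodes + 1
    outlet_node <- n_nodes
    pos <- c(pos, geom$length)
    edges_i <- c(edges_i, wn)
    edges_j <- c(edges_j, outlet_node)
    edges_g <- c(edges_g, 1 / lead_out)
  } else outlet_node <- wn

  list(pos = pos, n_nodes = n_nodes, well_nodes = well_nodes,
       inlet_node = inlet_node, outlet_node = outlet_node,
       edges_i = edges_i, edges_j = edges_j, edges_g = edges_g)
}

#' Net transmembrane (ultrafiltration) flow of a solution
#'
#' Sum of the per-segment membrane crossing flows; positive basal -> apical.
#' Equals basal inlet flow minus basal outlet flow to solver tolerance.
#'
#' @param solution a `flow_solution` from [solve_coupled_network()].
#' @return Net transmembrane flow, m^3/s.
#' @export
transmembrane_flow <- function(solution) {
  stopifnot(inherits(solution, "flow_solution"))
  sum(solution$transmembrane_flux)
}

#' Worst relative mass-conservation residual of a solution
#'
#' Interior nodal flow imbalance plus channel-level imbalance
#' (inlet - outlet -/+ net transmembrane flow), scaled by the largest
#' boundary flow.
#'
#' @param solution a `flow_solution`.
#' @return Dimensionless residual (0 = exact conservation).
#' @export
conservation_residual <- function(solution) {
  stopifnot(inherits(solution, "flow_solution"))
  q_tm <- transmembrane_flow(solution)
  scale <- max(abs(c(solution$q_inlet_apical, solution$q_inlet_basal,
                     solution$q_outlet_apical, solution$q_outlet_basal,
                     q_tm)), .Machine$double.xmin)
  imbalance <- c(
    solution$interior_residual,
    solution$q_inlet_apical + q_tm - solution$q_outlet_apical,
    solution$q_inlet_basal - q_tm - solution$q_outlet_basal)
  max(abs(imbalance)) / scale
}

#' @export
print.flow_solution <- function(x, ...) {
  q_tm <- transmembrane_flow(x)
  cat("<flow_solution>\n")
  cat(sprintf("  apical: in %.4g, out %.4g uL/min\n",
              m3_s_to_ul_min(x$q_inlet_apical),
              m3_s_to_ul_min(x$q_outlet_apical)))
  cat(sprintf("  basal:  in %.4g, out %.4g uL/min\n",
              m3_s_to_ul_min(x$q_inlet_basal),
              m3_s_to_ul_min(x$q_outlet_basal)))
  cat(sprintf("  transmembrane (basal->apical): %.4g uL/min over %d segments\n",
              m3_s_to_ul_min(q_tm), length(x$transmembrane_flux)))
  cat(sprintf("  conservation residual: %.2g\n", conservation_residual(x)))
  invisible(x)
}
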