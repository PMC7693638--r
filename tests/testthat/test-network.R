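test_that("symmetric chip with equal inlet flows has zero transmembrane flux", {
  chip <- symmetric_chip()
  sol <- solve_default(chip)
  expect_lt(abs(m3_s_to_ul_min(transmembrane_flow(sol))), 1e-9)
  expect_true(all(abs(m3_s_to_ul_min(sol$transmembrane_flux)) < 1e-9))
})

test_that("near-zero porosity decouples the channels into independent resistors", {
  chip <- default_chip()
  chip$membrane <- ref_membrane(porosity = 1e-12)
  p_in <- 500 # Pa
  cfg <- network_config(apical = inlet_pressure(p_in),
                        basal = inlet_pressure(p_in), n_segments = 16)
  sol <- solve_coupled_network(chip$apical, chip$basal, chip$membrane,
                               chip$fluid, cfg)
  expect_lt(abs(transmembrane_flow(sol)) / sol$q_inlet_apical, 1e-6)
  for (ch in c("apical", "basal")) {
    g <- chip[[ch]]
    fl <- chip$fluid
    r_tot <- channel_resistance(g, fl)$value +
      8 * fl$viscosity * (g$via_length_in + g$via_length_out) /
        (pi * g$via_radius^4)
    q <- if (ch == "apical") sol$q_inlet_apical else sol$q_inlet_basal
    expect_equal(q, p_in / r_tot, tolerance = 1e-9)
  }
})

test_that("one-segment solution matches a hand-assembled star circuit", {
  chip <- default_chip()
  fl <- chip$fluid
  r_memb <- membrane_resistance(chip$membrane, fl)$value
  qa <- ul_min_to_m3_s(100)
  qb <- ul_min_to_m3_s(60)

  # independent oracle: write the 6-node circuit equations explicitly
  leg <- function(g) {
    rp <- 12 * fl$viscosity / (g$width_b * g$height_h^3)
    via <- function(l) 8 * fl$viscosity * l / (pi * g$via_radius^4)
    list(lin = rp * g$well_offset + via(g$via_length_in),
         well = rp * g$well_span,
         lout = rp * (g$length - g$well_offset - g$well_span) +
           via(g$via_length_out))
  }
  a <- leg(chip$apical)
  b <- leg(chip$basal)
  gm <- 1 / (2 * r_memb) # membrane split over the two well nodes
  # unknowns: p_ai, p_a1, p_a2, p_bi, p_b1, p_b2 (outlets at 0)
  A <- matrix(0, 6, 6)
  rhs <- c(qa, 0, 0, qb, 0, 0)
  A[1, ] <- c(1 / a$lin, -1 / a$lin, 0, 0, 0, 0)
  A[2, ] <- c(-1 / a$lin, 1 / a$lin + 1 / a$well + gm, -1 / a$well,
              0, -gm, 0)
  A[3, ] <- c(0, -1 / a$well, 1 / a$well + 1 / a$lout + gm, 0, 0, -gm)
  A[4, ] <- c(0, 0, 0, 1 / b$lin, -1 / b$lin, 0)
  A[5, ] <- c(0, -gm, 0, -1 / b$lin, 1 / b$lin + 1 / b$well + gm,
              -1 / b$well)
  A[6, ] <- c(0, 0, -gm, 0, -1 / b$well,
              1 / b$well + 1 / b$lout + gm)
  p <- solve(A, rhs)
  q_tm_oracle <- gm * ((p[5] - p[2]) + (p[6] - p[3]))

  sol <- solve_default(chip, apical = 100, basal = 60, n_segments = 1)
  expect_equal(sol$node_pressures_apical[sol$well_nodes_apical],
               p[2:3], tolerance = 1e-10)
  expect_equal(sol$node_pressures_basal[sol$well_nodes_basal],
               p[5:6], tolerance = 1e-10)
  expect_equal(transmembrane_flow(sol), q_tm_oracle, tolerance = 1e-10)
})

test_that("mass is conserved to 1e-9 and pressure decreases along the flow", {
  for (flows in list(c(100, 100), c(30, 170), c(250, 10))) {
    sol <- solve_default(apical = flows[1], basal = flows[2])
    expect_lt(conservation_residual(sol), 1e-9)
    # transmembrane total equals basal inlet minus basal outlet
    expect_lt(abs(transmembrane_flow(sol) -
                    (sol$q_inlet_basal - sol$q_outlet_basal)) /
                abs(sol$q_inlet_basal), 1e-9)
    for (ch in c("apical", "basal")) {
      ord <- order(sol[[paste0("node_positions_", ch)]])
      p <- sol[[paste0("node_pressures_", ch)]][ord]
      expect_true(all(diff(p) <= 1e-12 * max(abs(p))))
    }
  }
})

test_that("the solution is linear in the boundary pressures", {
  chip <- default_chip()
  base_cfg <- function(alpha)
    network_config(apical = inlet_pressure(2000 * alpha),
                   basal = inlet_pressure(8000 * alpha), n_segments = 16)
  ref <- solve_coupled_network(chip$apical, chip$basal, chip$membrane,
                               chip$fluid, base_cfg(1))
  for (alpha in c(0.5, 2, 10)) {
    sol <- solve_coupled_network(chip$apical, chip$basal, chip$membrane,
                                 chip$fluid, base_cfg(alpha))
    expect_equal(transmembrane_flow(sol),
                 alpha * transmembrane_flow(ref), tolerance = 1e-9)
    expect_equal(sol$segment_flows_apical,
                 alpha * ref$segment_flows_apical, tolerance = 1e-9)
    expect_equal(sol$q_inlet_basal, alpha * ref$q_inlet_basal,
                 tolerance = 1e-9)
  }
})

test_that("transmembrane flow is mesh-converged and Ohmic in the membrane", {
  q64 <- m3_s_to_ul_min(transmembrane_flow(solve_default(n_segments = 64)))
  q128 <- m3_s_to_ul_min(transmembrane_flow(solve_default(n_segments = 128)))
  expect_lt(abs(q128 - q64) / abs(q64), 0.01)
  # doubling membrane resistance (half porosity) ~ halves the flow; the
  # membrane dominates the cross path, channel feedback adds a few percent
  chip <- default_chip()
  chip$membrane <- ref_membrane(porosity = 0.07)
  q_half <- m3_s_to_ul_min(transmembrane_flow(solve_default(chip)))
  q_ref <- m3_s_to_ul_min(transmembrane_flow(solve_default()))
  expect_equal(q_half / q_ref, 0.5, tolerance = 0.06)
  expect_gt(q_half / q_ref, 0.5) # feedback can only weaken the halving
})
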