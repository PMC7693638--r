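test_that("pressure-flow fit recovers a known resistance from clean data", {
  r_true <- 3e12
  p <- seq(0, 15000, length.out = 11)
  q <- p / r_true
  fit <- fit_pq_line(p, q)
  expect_false(fit$degenerate)
  expect_lt(abs(fit$resistance - r_true) / r_true, 1e-3)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # instrument-unit interface agrees with the SI one
  fit2 <- fit_pq_line(pa_to_mbar(p), m3_s_to_ul_min(q),
                      pressure_unit = "mbar", flow_unit = "ul_min")
  expect_equal(fit2$resistance, fit$resistance, tolerance = 1e-9)
})

test_that("degenerate and underdetermined sweeps are rejected or flagged", {
  expect_error(fit_pq_line(c(0, 100), c(0, 1e-9)), "3 distinct")
  expect_error(fit_pq_line(rep(100, 5), rep(1e-9, 5)), "3 distinct")
  flat <- fit_pq_line(seq(0, 15000, length.out = 5), rep(0, 5))
  expect_true(flat$degenerate)
  expect_true(is.na(flat$resistance))
})

test_that("fitting generated flow sweeps recovers the scenario's resistance", {
  # noiseless: per-pressure means are exactly P/R
  sc0 <- synthetic_scenario(seed = 7, flow_noise_frac = 0)
  rec <- gen_flow_recordings(sc0)
  means <- aggregate(flow_ul_min ~ pressure_mbar, rec, mean)
  fit <- fit_pq_line(means$pressure_mbar, means$flow_ul_min,
                     pressure_unit = "mbar", flow_unit = "ul_min")
  expect_lt(abs(fit$resistance - sc0$r_channel_true) / sc0$r_channel_true,
            1e-3)
  # 2% full-scale sensor noise: resistance within 5% in >= 95% of replicates
  ok <- vapply(1:200, function(s) {
    sc <- synthetic_scenario(seed = s, flow_noise_frac = 0.02)
    rec <- gen_flow_recordings(sc)
    means <- aggregate(flow_ul_min ~ pressure_mbar, rec, mean)
    fit <- fit_pq_line(means$pressure_mbar, means$flow_ul_min,
                       pressure_unit = "mbar", flow_unit = "ul_min")
    abs(fit$resistance - sc$r_channel_true) / sc$r_channel_true < 0.05
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("membrane permeability round-trips through the network model", {
  chip <- default_chip()
  ops <- data.frame(apical_flow_ul_min = c(100, 50, 150),
                    basal_flow_ul_min = c(100, 150, 100))
  ops$q_tm_ul_min <- vapply(seq_len(nrow(ops)), function(i)
    m3_s_to_ul_min(transmembrane_flow(solve_default(
      chip, ops$apical_flow_ul_min[i], ops$basal_flow_ul_min[i],
      n_segments = 16))), numeric(1))
  # start the search from a mis-specified template (5x the truth)
  template <- ref_membrane(porosity = 0.7)
  fit <- fit_membrane_permeability(ops, chip$apical, chip$basal, template,
                                   chip$fluid, n_segments = 16)
  k_true <- permeability(chip$membrane)
  expect_true(fit$identifiable)
  expect_lt(abs(fit$k - k_true) / k_true, 0.005)
})

test_that("permeability fit flags non-identifiable inputs", {
  chip <- symmetric_chip()
  ops <- data.frame(apical_flow_ul_min = 100, basal_flow_ul_min = 100,
                    q_tm_ul_min = 0)
  fit <- fit_membrane_permeability(ops, chip$apical, chip$basal,
                                   chip$membrane, chip$fluid)
  expect_false(fit$identifiable) # no gradient: k cannot be estimated
  chip2 <- default_chip()
  ops2 <- data.frame(apical_flow_ul_min = c(100, 50),
                     basal_flow_ul_min = c(100, 150), q_tm_ul_min = c(0, 0))
  fit2 <- fit_membrane_permeability(ops2, chip2$apical, chip2$basal,
                                    chip2$membrane, chip2$fluid)
  expect_false(fit2$identifiable) # zero flow under gradient: k -> 0
  expect_lt(fit2$k, permeability(chip2$membrane) / 100)
})

test_that("permeability recovery tolerates multiplicative noise", {
  chip <- default_chip()
  k_true <- permeability(chip$membrane)
  ops0 <- data.frame(
    apical_flow_ul_min = c(100, 50, 100, 150, 100, 75),
    basal_flow_ul_min = c(100, 100, 50, 100, 150, 125))
  ops0$q_true <- vapply(seq_len(nrow(ops0)), function(i)
    m3_s_to_ul_min(transmembrane_flow(solve_default(
      chip, ops0$apical_flow_ul_min[i], ops0$basal_flow_ul_min[i],
      n_segments = 8))), numeric(1))
  errs <- vapply(1:100, function(s) {
    set.seed(s)
    ops <- ops0
    ops$q_tm_ul_min <- ops0$q_true * exp(rnorm(nrow(ops0), sd = 0.05))
    fit <- fit_membrane_permeability(ops, chip$apical, chip$basal,
                                     chip$membrane, chip$fluid,
                                     n_segments = 8)
    abs(fit$k - k_true) / k_true
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})
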