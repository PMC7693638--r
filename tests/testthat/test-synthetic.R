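test_that("generators are deterministic in (seed, scenario) and leave the RNG alone", {
  sc <- synthetic_scenario(seed = 11)
  set.seed(999)
  before <- .Random.seed
  a <- gen_flow_recordings(sc)
  expect_identical(.Random.seed, before) # caller's RNG state untouched
  b <- gen_flow_recordings(sc)
  expect_identical(a, b)
  expect_identical(gen_deflection_sweep(sc), gen_deflection_sweep(sc))
  expect_identical(gen_filtration_readouts(sc), gen_filtration_readouts(sc))
  # different seeds differ, same per-pressure means within CLT tolerance
  sc2 <- synthetic_scenario(seed = 12)
  c <- gen_flow_recordings(sc2)
  expect_false(identical(a$flow_ul_min, c$flow_ul_min))
  ma <- aggregate(flow_ul_min ~ pressure_mbar, a, mean)
  mc <- aggregate(flow_ul_min ~ pressure_mbar, c, mean)
  sem <- sc$flow_noise_frac * sc$flow_full_scale_ul_min / sqrt(600)
  expect_true(all(abs(ma$flow_ul_min - mc$flow_ul_min) < 8 * sem))
})

test_that("noiseless flow recordings sit exactly on P/R", {
  sc <- synthetic_scenario(seed = 3, flow_noise_frac = 0)
  rec <- gen_flow_recordings(sc)
  expect_equal(nrow(rec), 11 * 600)
  q_expect <- m3_s_to_ul_min(mbar_to_pa(rec$pressure_mbar) /
                               sc$r_channel_true)
  expect_equal(rec$flow_ul_min, q_expect, tolerance = 1e-12)
})

test_that("deflection sweeps are monotone power laws anchored at 4% strain", {
  sc <- synthetic_scenario(seed = 5, focal_sd_um = 0)
  sw <- gen_deflection_sweep(sc)
  expect_equal(nrow(sw), 22)
  expect_equal(sw$deflection_mm[1], 0)
  expect_true(all(diff(sw$deflection_mm) > 0))
  curve <- strain_sweep(sw, default_planform())
  expect_equal(curve$strain[22], 0.04, tolerance = 1e-9)
  # with reading noise the deflections stay non-negative
  swn <- gen_deflection_sweep(synthetic_scenario(seed = 5, focal_sd_um = 50))
  expect_true(all(swn$deflection_mm >= 0))
})

test_that("TEER time courses order conditions as the culture biology dictates", {
  sc <- synthetic_scenario(seed = 8, ohm_sd = 0)
  tc <- lapply(c("podocyte_only", "endothelial_only", "coculture"),
               function(cond) gen_teer_timecourse(sc, cond))
  final <- vapply(tc, function(d)
    teer(d$r_meas_ohm[nrow(d)], sc$r_blank_true, d$m_area_cm2[1]),
    numeric(1))
  expect_true(final[1] < final[2] && final[2] < final[3])
  # co-culture only slightly above endothelial-only
  expect_lte(final[3] / final[2], 1.3)
  # day 0 is at blank level
  day0 <- vapply(tc, function(d) d$teer_true[1], numeric(1))
  expect_equal(day0, rep(0, 3))
  expect_error(gen_teer_timecourse(sc, "astrocytes"))
})

test_that("filtration readouts recover the sieving ratios through batch_assay", {
  sc <- synthetic_scenario(seed = 21, conc_cv = 0)
  out <- batch_assay(gen_filtration_readouts(sc))
  sv <- sc$sieving
  for (sol in names(sv)) {
    for (cond in c("control", "S1P")) {
      got <- out$normalized_filtration[out$solute == sol &
                                         out$condition == cond]
      expect_equal(got, sv[[sol]][[cond]] / sv[[sol]][["blank"]],
                   tolerance = 1e-12)
    }
  }
  # sieving identical everywhere -> all normalized filtrations 1
  sc1 <- synthetic_scenario(seed = 22, conc_cv = 0,
                            sieving = list(albumin = c(blank = 1,
                                                       control = 1,
                                                       S1P = 1)))
  out1 <- batch_assay(gen_filtration_readouts(sc1, solutes = "albumin"))
  expect_true(all(out1$normalized_filtration == 1))
})

test_that("generated tables parse through the package's own CSV dialects", {
  dir <- withr::local_tempdir()
  paths <- write_fixtures(synthetic_scenario(seed = 2), dir)
  expect_length(paths, 4)
  sw <- read_deflection_sweep(file.path(dir, "deflection_sweep.csv"))
  expect_s3_class(strain_sweep(sw, default_planform()), "strain_curve")
  rd <- read_assay_readouts(file.path(dir, "filtration_readouts.csv"))
  expect_gt(nrow(batch_assay(rd)), 0)
  rec <- utils::read.csv(file.path(dir, "flow_recordings.csv"))
  means <- aggregate(flow_ul_min ~ pressure_mbar, rec, mean)
  fit <- fit_pq_line(means$pressure_mbar, means$flow_ul_min,
                     pressure_unit = "mbar", flow_unit = "ul_min")
  expect_false(fit$degenerate)
  # regenerating into a second tree is byte-identical
  dir2 <- withr::local_tempdir()
  write_fixtures(synthetic_scenario(seed = 2), dir2)
  for (f in basename(paths)) {
    expect_identical(readBin(file.path(dir, f), "raw",
                             file.size(file.path(dir, f))),
                     readBin(file.path(dir2, f), "raw",
                             file.size(file.path(dir2, f))),
                     info = f)
  }
})
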