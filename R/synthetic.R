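#' Seeded synthetic-data scenario
#'
#' Ground truth and per-instrument noise model for the synthetic generators.
#' Every generator draws from its own RNG stream derived from `seed`, so a
#' given (seed, scenario) pair reproduces byte-identical tables without
#' disturbing the caller's RNG state.
#'
#' Noise models: additive Gaussian for the flow sensor (sd as a fraction of
#' instrument full scale) and focal-distance/ohmmeter readings;
#' multiplicative log-normal (unit mean) for concentrations. Sieving
#' coefficients are per-condition truths in `[0, 1]`; the injury scenario
#' defaults to a doubled albumin sieving with inulin untouched.
#'
#' @param seed integer RNG seed.
#' @param flow_noise_frac flow-sensor noise sd as a fraction of full scale.
#' @param flow_full_scale_ul_min flow-sensor full scale, uL/min.
#' @param focal_sd_um focal-distance reading sd, micrometers.
#' @param ohm_sd ohmmeter reading sd, Ohm.
#' @param conc_cv coefficient of variation of concentration readouts.
#' @param r_channel_true true system hydraulic resistance seen by the flow
#'   sweep (chip + tubing + sensor), Pa.s/m^3.
#' @param compliance_c1 deflection power-law coefficient (mm/mbar^c2);
#'   `NULL` = choose so the 315 mbar endpoint reaches 4% bi-axial strain on
#'   the default planform.
#' @param compliance_c2 deflection power-law exponent in (0, 1].
#' @param teer_final named final-day TEER truths (Ohm.cm^2) per condition.
#' @param r_blank_true true blank-membrane resistance, Ohm.
#' @param m_area membrane area for TEER records, cm^2.
#' @param sieving named list per solute of named per-condition sieving
#'   coefficients in `[0, 1]`.
#' @param feed_mg_ml named basal feed concentrations, mg/mL.
#' @param apical_volume_ul apical volume collected per run, uL.
#' @return An object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(
    seed = 1L,
    flow_noise_frac = 0.02,
    flow_full_scale_ul_min = 1000,
    focal_sd_um = 2,
    ohm_sd = 2,
    conc_cv = 0.1,
    r_channel_true = 3e12,
    compliance_c1 = NULL,
    compliance_c2 = 1 / 3,
    teer_final = c(podocyte_only = 12, endothelial_only = 40,
                   coculture = 48),
    r_blank_true = 100,
    m_area = 0.336,
    sieving = list(
      albumin = c(blank = 0.9, control = 0.25, S1P = 0.5),
      inulin = c(blank = 0.95, control = 0.95, S1P = 0.95)),
    feed_mg_ml = c(albumin = 2, inulin = 0.1),
    apical_volume_ul = 120) {
  stopifnot(flow_noise_frac >= 0, focal_sd_um >= 0, ohm_sd >= 0,
            conc_cv >= 0, r_channel_true > 0,
            compliance_c2 > 0, compliance_c2 <= 1)
  if (any(unlist(sieving) < 0) || any(unlist(sieving) > 1))
    stop("sieving coefficients must lie in [0, 1]", call. = FALSE)
  if (!all(c("podocyte_only", "endothelial_only", "coculture") %in%
           names(teer_final)))
    stop("teer_final must name conditions podocyte_only, endothelial_only, ",
         "coculture", call. = FALSE)
  structure(as.list(environment()), class = "synthetic_scenario")
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat(sprintf("<synthetic_scenario> seed %d; flow noise %.3g FS, conc CV %.3g\n",
              x$seed, x$flow_noise_frac, x$conc_cv))
  invisible(x)
}

# Evaluate code under a derived seed, restoring the caller's RNG state.
# stream_offset keeps the four generators statistically independent.
with_scenario_seed <- function(scenario, stream_offset, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((scenario$seed + stream_offset) %% .Machine$integer.max)
  code
}

#' Synthetic pressure-flow recordings
#'
#' Emulates a flow-meter sweep: at each applied pressure the true flow is
#' P / R_true and each sample adds i.i.d. Gaussian sensor noise scaled to
#' instrument full scale. 60 s recordings over a 0-150 mbar grid by default.
#'
#' @param scenario a [synthetic_scenario()].
#' @param pressures_mbar applied pressure grid.
#' @param duration_s recording length per pressure.
#' @param sample_rate samples per second.
#' @return data.frame `time_s`, `pressure_mbar`, `flow_ul_min`.
#' @export
gen_flow_recordings <- function(scenario, pressures_mbar = seq(0, 150, by = 15),
                                duration_s = 60, sample_rate = 10) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  n_samp <- round(duration_s * sample_rate)
  t <- (seq_len(n_samp) - 1) / sample_rate
  sd_ul <- scenario$flow_noise_frac * scenario$flow_full_scale_ul_min
  with_scenario_seed(scenario, 101L, {
    do.call(rbind, lapply(pressures_mbar, function(p) {
      q_true <- m3_s_to_ul_min(mbar_to_pa(p) / scenario$r_channel_true)
      data.frame(time_s = t, pressure_mbar = p,
                 flow_ul_min = q_true + stats::rnorm(n_samp, sd = sd_ul))
    }))
  })
}

# Power-law compliance coefficient: endpoint anchored at 4% strain unless
# the scenario fixes c1 explicitly.
compliance_c1 <- function(scenario, planform = default_planform(),
                          p_max_mbar = 315) {
  if (!is.null(scenario$compliance_c1)) return(scenario$compliance_c1)
  deflection_for_strain(0.04, planform) / p_max_mbar^scenario$compliance_c2
}

#' Synthetic pressure-deflection sweep
#'
#' Deflection follows a monotone power law a(P) = c1 * P^c2 through the
#' origin (a modeling convenience, not a membrane-physics claim), plus
#' focal-distance reading noise, over a 0-315 mbar grid in 15 mbar steps
#' (22 records).
#'
#' @param scenario a [synthetic_scenario()].
#' @param pressures_mbar sweep grid.
#' @param planform planform used to anchor the default compliance.
#' @return data.frame `pressure_mbar`, `deflection_mm`.
#' @export
gen_deflection_sweep <- function(scenario,
                                 pressures_mbar = seq(0, 315, by = 15),
                                 planform = default_planform()) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  c1 <- compliance_c1(scenario, planform, max(pressures_mbar))
  a_true <- c1 * pressures_mbar^scenario$compliance_c2
  with_scenario_seed(scenario, 202L, {
    noise <- stats::rnorm(length(a_true), sd = scenario$focal_sd_um / 1000)
    data.frame(pressure_mbar = pressures_mbar,
               deflection_mm = pmax(a_true + noise, 0))
  })
}

#' Synthetic TEER time course for barrier-formation conditions
#'
#' Logistic coverage growth mapped to resistance, with the condition
#' ordering coculture >= endothelial_only >= podocyte_only in expectation at
#' the final day (podocytes terminally differentiate and barely proliferate;
#' endothelial cells grow confluent; the co-culture ends slightly above
#' endothelial-only). Day 0 starts at blank level (TEER = 0) exactly in
#' expectation.
#'
#' @param scenario a [synthetic_scenario()].
#' @param condition one of `"podocyte_only"`, `"endothelial_only"`,
#'   `"coculture"`.
#' @param days measurement days.
#' @param growth_rate,t_mid logistic growth rate (1/day) and midpoint (day).
#' @return data.frame `day`, `condition`, `r_blank_ohm`, `r_meas_ohm`,
#'   `m_area_cm2`, `teer_true`.
#' @export
gen_teer_timecourse <- function(scenario, condition, days = 0:5,
                                growth_rate = 1.5, t_mid = 2.5) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  condition <- match.arg(condition, names(scenario$teer_final))
  final <- scenario$teer_final[[condition]]
  logis <- function(t) 1 / (1 + exp(-growth_rate * (t - t_mid)))
  t_end <- max(days)
  cover <- (logis(days) - logis(0)) / (logis(t_end) - logis(0))
  teer_true <- final * cover
  with_scenario_seed(scenario, 303L + match(condition,
                                            names(scenario$teer_final)), {
    r_blank <- scenario$r_blank_true +
      stats::rnorm(length(days), sd = scenario$ohm_sd)
    r_meas <- scenario$r_blank_true + teer_true / scenario$m_area +
      stats::rnorm(length(days), sd = scenario$ohm_sd)
    data.frame(day = days, condition = condition,
               r_blank_ohm = r_blank, r_meas_ohm = pmax(r_meas, 0),
               m_area_cm2 = scenario$m_area, teer_true = teer_true)
  })
}

#' Synthetic filtration assay readouts
#'
#' Paired apical/basal outflow concentrations for each (solute, condition,
#' replicate): the basal outflow sits at the feed concentration and the
#' apical outflow at sieving * feed, each under multiplicative log-normal
#' noise with unit mean. The default truths encode the injury scenario:
#' albumin sieving doubled under S1P, inulin (freely filtered) unchanged.
#'
#' @param scenario a [synthetic_scenario()].
#' @param conditions condition labels; must exist in `scenario$sieving`.
#' @param solutes solute labels; must exist in `scenario$sieving`.
#' @param n_replicates replicates per (solute, condition).
#' @return data.frame `solute`, `condition`, `replicate`, `conc_apical`,
#'   `apical_volume_ul`, `conc_basal` (concentrations in mg/mL).
#' @export
gen_filtration_readouts <- function(scenario,
                                    conditions = c("blank", "control", "S1P"),
                                    solutes = c("albumin", "inulin"),
                                    n_replicates = 3) {
  stopifnot(inherits(scenario, "synthetic_scenario"), n_replicates >= 1)
  sdlog <- sqrt(log(1 + scenario$conc_cv^2))
  lognoise <- function(n) {
    if (sdlog == 0) rep(1, n) else
      exp(stats::rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
  }
  with_scenario_seed(scenario, 404L, {
    grid <- expand.grid(replicate = seq_len(n_replicates),
                        condition = conditions, solute = solutes,
                        stringsAsFactors = FALSE)
    feed <- scenario$feed_mg_ml[grid$solute]
    s <- mapply(function(sol, cond) {
      sv <- scenario$sieving[[sol]]
      if (is.null(sv) || !cond %in% names(sv))
        stop("no sieving truth for solute '", sol, "', condition '", cond,
             "'", call. = FALSE)
      sv[[cond]]
    }, grid$solute, grid$condition)
    n <- nrow(grid)
    data.frame(solute = grid$solute, condition = grid$condition,
               replicate = grid$replicate,
               conc_apical = s * feed * lognoise(n),
               apical_volume_ul = scenario$apical_volume_ul,
               conc_basal = feed * lognoise(n))
  })
}
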