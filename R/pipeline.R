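#' Default two-channel chip description
#'
#' The documented reference configuration of the milled two-channel device:
#' apical channel 6 mm wide, basal 4.5 mm, both 0.5 mm high and 35 mm long
#' with the 6 mm culture-well region centered; water as working fluid; a
#' 3 um-pore track-etched membrane (pore radius 1.5 um, thickness 10 um,
#' porosity 0.14 from a nominal 2e6 pores/cm2) wetted over the 6 x 4.5 mm
#' well overlap (27 mm^2). Port access bores are part of the network: the
#' apical channel is reached through one 0.125-inch acrylic layer
#' (3.175 mm), the basal channel -- milled into the bottom piece of the
#' stack -- through two (6.35 mm); bore radius 0.5 mm. Every element is
#' overridable via [read_chip_config()] or by replacing list entries, and
#' every reported result echoes the parameter set used.
#'
#' @return list with `fluid`, `apical`, `basal`, `membrane`.
#' @export
default_chip <- function() {
  list(
    fluid = water(),
    apical = channel_geometry(width_b = 6e-3, height_h = 0.5e-3,
                              length = 35e-3, well_span = 6e-3,
                              via_length_in = 3.175e-3,
                              via_length_out = 3.175e-3,
                              via_radius = 0.5e-3),
    basal = channel_geometry(width_b = 4.5e-3, height_h = 0.5e-3,
                             length = 35e-3, well_span = 6e-3,
                             via_length_in = 6.35e-3,
                             via_length_out = 6.35e-3,
                             via_radius = 0.5e-3),
    membrane = membrane_spec(pore_radius = 1.5e-6, thickness = 10e-6,
                             porosity = 0.14, area = 27e-6))
}

chip_params_text <- function(chip) {
  c(sprintf("fluid: viscosity %.4g Pa.s, density %.4g kg/m^3",
            chip$fluid$viscosity, chip$fluid$density),
    vapply(c("apical", "basal"), function(ch) {
      g <- chip[[ch]]
      sprintf(paste0("%s: width %.4g mm, height %.4g mm, length %.4g mm, ",
                     "well %.4g mm @ %.4g mm, vias %.4g/%.4g mm r %.4g mm"),
              ch, g$width_b * 1e3, g$height_h * 1e3, g$length * 1e3,
              g$well_span * 1e3, g$well_offset * 1e3,
              g$via_length_in * 1e3, g$via_length_out * 1e3,
              g$via_radius * 1e3)
    }, character(1)),
    sprintf(paste0("membrane: pore radius %.4g um, thickness %.4g um, ",
                   "porosity %.4g, area %.4g mm^2"),
            chip$membrane$pore_radius * 1e6, chip$membrane$thickness * 1e6,
            chip$membrane$porosity, chip$membrane$area * 1e6))
}

write_manifest <- function(out_dir, inputs = character()) {
  md5 <- tools::md5sum(inputs)
  names(md5) <- basename(inputs)
  manifest <- list(
    package = "mpsflow",
    version = as.character(utils::packageVersion("mpsflow")),
    input_md5 = as.list(md5),
    outputs = list.files(out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run the chip design analysis
#'
#' Computes channel resistances, wall shear stresses at the configured
#' operating flows, membrane pore/whole resistances and permeability, solves
#' the coupled network, and writes `solution.csv`, a human-readable
#' `summary.txt` (including full parameter provenance) and a
#' `manifest.json` into `out_dir`. Reruns with the same configuration are
#' byte-identical.
#'
#' @param chip chip description from [default_chip()] or
#'   [read_chip_config()].
#' @param apical_flow_ul_min,basal_flow_ul_min imposed inlet flows, uL/min.
#' @param n_segments solver discretization.
#' @param out_dir output directory (created if missing); `NULL` = no files.
#' @return A `design_report` list: `solution`, `q_tm_ul_min`, `shear_pa`,
#'   `resistances`, `chip`.
#' @export
run_design <- function(chip = default_chip(),
                       apical_flow_ul_min = 100, basal_flow_ul_min = 100,
                       n_segments = 64, out_dir = NULL) {
  cfg <- network_config(
    apical = inlet_flow(ul_min_to_m3_s(apical_flow_ul_min)),
    basal = inlet_flow(ul_min_to_m3_s(basal_flow_ul_min)),
    n_segments = n_segments)
  sol <- solve_coupled_network(chip$apical, chip$basal, chip$membrane,
                               chip$fluid, cfg)
  q_tm <- m3_s_to_ul_min(transmembrane_flow(sol))
  shear <- c(
    apical = wall_shear_stress(ul_min_to_m3_s(apical_flow_ul_min),
                               chip$apical, chip$fluid),
    basal = wall_shear_stress(ul_min_to_m3_s(basal_flow_ul_min),
                              chip$basal, chip$fluid))
  res <- list(
    channel_apical = channel_resistance(chip$apical, chip$fluid),
    channel_basal = channel_resistance(chip$basal, chip$fluid),
    pore = pore_resistance(chip$membrane, chip$fluid),
    membrane = membrane_resistance(chip$membrane, chip$fluid))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_solution_csv(sol, file.path(out_dir, "solution.csv"))
    summary_lines <- c(
      "two-channel membrane chip: design analysis",
      "", "parameters:", paste(" ", chip_params_text(chip)),
      sprintf("  operating point: apical %.4g, basal %.4g uL/min; %d segments",
              apical_flow_ul_min, basal_flow_ul_min, n_segments),
      "", "results:",
      sprintf("  channel resistance apical: %.6g Pa.s/m^3",
              res$channel_apical$value),
      sprintf("  channel resistance basal:  %.6g Pa.s/m^3",
              res$channel_basal$value),
      sprintf("  single-pore resistance:    %.6g Pa.s/m^3", res$pore$value),
      sprintf("  membrane resistance:       %.6g Pa.s/m^3",
              res$membrane$value),
      sprintf("  membrane permeability:     %.6g m^2",
              permeability(chip$membrane)),
      sprintf("  wall shear stress apical:  %.6g Pa", shear[["apical"]]),
      sprintf("  wall shear stress basal:   %.6g Pa", shear[["basal"]]),
      sprintf("  transmembrane flow:        %.6g uL/min (basal -> apical)",
              q_tm),
      sprintf("  conservation residual:     %.3g", conservation_residual(sol)))
    writeLines(summary_lines, file.path(out_dir, "summary.txt"))
    write_manifest(out_dir,
                   inputs = file.path(out_dir, c("solution.csv",
                                                 "summary.txt")))
  }
  structure(list(solution = sol, q_tm_ul_min = q_tm, shear_pa = shear,
                 resistances = res, chip = chip),
            class = "design_report")
}

#' @export
print.design_report <- function(x, ...) {
  cat("<design_report>\n")
  cat(sprintf("  transmembrane flow: %.4g uL/min\n", x$q_tm_ul_min))
  cat(sprintf("  shear: apical %.4g Pa, basal %.4g Pa\n",
              x$shear_pa[["apical"]], x$shear_pa[["basal"]]))
  invisible(x)
}

#' Run the batch filtration analysis on a readout table
#'
#' Reads the assay CSV (or takes a data.frame), runs [batch_assay()], writes
#' `filtration.csv` and `manifest.json`, and logs warnings for negative
#' cell-layer resistances or clamped concentrations raised downstream.
#'
#' @param readouts path to an assay CSV or a data.frame in the
#'   [read_assay_readouts()] dialect.
#' @param blank_label condition label of the blank rows.
#' @param out_dir output directory; `NULL` = no files.
#' @return The tidy result table from [batch_assay()].
#' @export
run_assay <- function(readouts, blank_label = "blank", out_dir = NULL) {
  if (is.character(readouts)) readouts <- read_assay_readouts(readouts)
  result <- batch_assay(readouts, blank_label = blank_label)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(result, file.path(out_dir, "filtration.csv"),
                     row.names = FALSE, quote = FALSE)
    write_manifest(out_dir, inputs = file.path(out_dir, "filtration.csv"))
  }
  result
}

#' Materialize a full synthetic demo dataset tree
#'
#' Writes one file per generator: flow recordings, deflection sweep, TEER
#' time courses (all conditions), and filtration readouts, in the exact CSV
#' dialects the analysis functions consume.
#'
#' @param scenario a [synthetic_scenario()].
#' @param out_dir output directory.
#' @return Character vector of written paths, invisibly.
#' @export
write_fixtures <- function(scenario = synthetic_scenario(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  p <- file.path(out_dir, "flow_recordings.csv")
  utils::write.csv(gen_flow_recordings(scenario), p, row.names = FALSE,
                   quote = FALSE)
  paths <- c(paths, p)
  p <- file.path(out_dir, "deflection_sweep.csv")
  write_deflection_sweep(gen_deflection_sweep(scenario), p)
  paths <- c(paths, p)
  p <- file.path(out_dir, "teer_timecourse.csv")
  teer_df <- do.call(rbind, lapply(names(scenario$teer_final), function(cond)
    gen_teer_timecourse(scenario, cond)))
  utils::write.csv(teer_df, p, row.names = FALSE, quote = FALSE)
  paths <- c(paths, p)
  p <- file.path(out_dir, "filtration_readouts.csv")
  write_assay_readouts(gen_filtration_readouts(scenario), p)
  paths <- c(paths, p)
  invisible(paths)
}
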