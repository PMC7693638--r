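#' Read a chip configuration file
#'
#' JSON schema with all lengths in millimeters (pore radius and thickness in
#' micrometers), converted to SI internally. Unknown keys are rejected so
#' typos cannot silently fall back to defaults.
#'
#' Schema (all blocks required unless noted):
#' \preformatted{
#' {
#'   "fluid":    {"viscosity_pa_s": 0.001, "density_kg_m3": 1000},
#'   "apical":   {"width_mm": 6, "height_mm": 0.5, "length_mm": 35,
#'                "well_span_mm": 6, "well_offset_mm": 14.5,   # optional
#'                "via_length_in_mm": 3.175, "via_length_out_mm": 3.175,
#'                "via_radius_mm": 0.5},                        # optional
#'   "basal":    { ... same keys ... },
#'   "membrane": {"pore_radius_um": 1.5, "thickness_um": 10,
#'                "porosity": 0.14, "area_mm2": 27}
#' }
#' }
#'
#' @param path path to the JSON file.
#' @return list with elements `fluid`, `apical`, `basal`, `membrane` (typed
#'   objects ready for [solve_coupled_network()]).
#' @export
read_chip_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known_top <- c("fluid", "apical", "basal", "membrane")
  reject_unknown(names(raw), known_top, "config")
  miss <- setdiff(known_top, names(raw))
  if (length(miss))
    stop("config lacks block(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  chip_from_lists(raw$fluid, raw$apical, raw$basal, raw$membrane)
}

reject_unknown <- function(got, known, where) {
  unknown <- setdiff(got, known)
  if (length(unknown))
    stop("unknown key(s) in ", where, ": ", paste(unknown, collapse = ", "),
         call. = FALSE)
}

parse_channel_block <- function(x, where) {
  known <- c("width_mm", "height_mm", "length_mm", "well_span_mm",
             "well_offset_mm", "via_length_in_mm", "via_length_out_mm",
             "via_radius_mm")
  reject_unknown(names(x), known, where)
  need <- c("width_mm", "height_mm", "length_mm", "well_span_mm")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop(where, " lacks key(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  mm <- 1e-3
  args <- list(width_b = x$width_mm * mm, height_h = x$height_mm * mm,
               length = x$length_mm * mm, well_span = x$well_span_mm * mm)
  if (!is.null(x$well_offset_mm)) args$well_offset <- x$well_offset_mm * mm
  if (!is.null(x$via_length_in_mm)) args$via_length_in <- x$via_length_in_mm * mm
  if (!is.null(x$via_length_out_mm)) args$via_length_out <- x$via_length_out_mm * mm
  if (!is.null(x$via_radius_mm)) args$via_radius <- x$via_radius_mm * mm
  do.call(channel_geometry, args)
}

chip_from_lists <- function(fluid, apical, basal, membrane) {
  reject_unknown(names(fluid), c("viscosity_pa_s", "density_kg_m3"), "fluid")
  reject_unknown(names(membrane),
                 c("pore_radius_um", "thickness_um", "porosity", "area_mm2"),
                 "membrane")
  list(
    fluid = fluid_props(fluid$viscosity_pa_s, fluid$density_kg_m3),
    apical = parse_channel_block(apical, "apical"),
    basal = parse_channel_block(basal, "basal"),
    membrane = membrane_spec(membrane$pore_radius_um * 1e-6,
                             membrane$thickness_um * 1e-6,
                             membrane$porosity,
                             membrane$area_mm2 * 1e-6))
}

#' Export a flow solution as CSV
#'
#' One row per node and channel: node index, axial position (mm), pressure
#' (Pa); transmembrane flux rows carry the per-segment membrane crossing
#' flow (uL/min, positive basal to apical).
#'
#' @param solution a `flow_solution`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_solution_csv <- function(solution, path) {
  stopifnot(inherits(solution, "flow_solution"))
  node_rows <- function(ch) {
    ord <- order(solution[[paste0("node_positions_", ch)]])
    data.frame(
      record = "node", channel = ch,
      index = seq_along(ord),
      position_mm = solution[[paste0("node_positions_", ch)]][ord] * 1e3,
      pressure_pa = solution[[paste0("node_pressures_", ch)]][ord],
      flux_ul_min = NA_real_)
  }
  wa <- solution$well_nodes_apical
  pos <- solution$node_positions_apical
  seg_mid <- (pos[wa[-length(wa)]] + pos[wa[-1]]) / 2
  tm <- data.frame(
    record = "transmembrane", channel = "membrane",
    index = seq_along(solution$transmembrane_flux),
    position_mm = seg_mid * 1e3,
    pressure_pa = NA_real_,
    flux_ul_min = m3_s_to_ul_min(solution$transmembrane_flux))
  utils::write.csv(rbind(node_rows("apical"), node_rows("basal"), tm),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a deflection sweep CSV
#'
#' Columns `pressure_mbar`, `deflection_um`; deflection converted to mm to
#' match the planform unit used by [strain_sweep()].
#'
#' @param path CSV path.
#' @return data.frame `pressure_mbar`, `deflection_mm`.
#' @export
read_deflection_sweep <- function(path) {
  df <- utils::read.csv(path)
  need <- c("pressure_mbar", "deflection_um")
  if (!all(need %in% names(df)))
    stop("deflection CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  data.frame(pressure_mbar = df$pressure_mbar,
             deflection_mm = df$deflection_um / 1000)
}

#' @rdname read_deflection_sweep
#' @param sweep data.frame `pressure_mbar`, `deflection_mm`.
#' @export
write_deflection_sweep <- function(sweep, path) {
  utils::write.csv(
    data.frame(pressure_mbar = sweep$pressure_mbar,
               deflection_um = sweep$deflection_mm * 1000),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write assay readout tables
#'
#' CSV dialect consumed by [batch_assay()]: columns `solute`, `condition`,
#' `conc_apical`, `apical_volume_ul`, `conc_basal` (plus optional
#' `replicate`).
#'
#' @param path CSV path.
#' @param readouts data.frame in the dialect above.
#' @return data.frame / `path` invisibly.
#' @export
read_assay_readouts <- function(path) {
  df <- utils::read.csv(path)
  need <- c("solute", "condition", "conc_apical", "apical_volume_ul",
            "conc_basal")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("assay CSV lacks column(s): ", paste(miss, collapse = ", "),
         " (", path, ")", call. = FALSE)
  df
}

#' @rdname read_assay_readouts
#' @export
write_assay_readouts <- function(readouts, path) {
  utils::write.csv(readouts, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
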