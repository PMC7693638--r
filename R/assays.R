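#' Transepithelial/transendothelial electrical resistance (TEER)
#'
#' Ohm's-law method: the cell-layer resistance is the measured resistance
#' minus the blank-membrane resistance, and TEER is that difference times
#' the membrane area: TEER = (R_meas - R_blank) * M_area, in Ohm.cm^2.
#' A negative cell-layer resistance (cells measuring below blank) is a
#' common measurement artifact: it is returned as-is with a warning rather
#' than raised, so batch runs do not crash.
#'
#' @param r_meas measured resistance with cells, Ohm (>= 0; vectorized).
#' @param r_blank blank-membrane resistance, Ohm (>= 0).
#' @param m_area membrane area, cm^2 (> 0). No default: insert formats
#'   differ (0.336 cm^2 for the 24-well transwell format).
#' @return TEER in Ohm.cm^2.
#' @examples
#' teer(150, 100, 0.336) # 16.8 Ohm.cm^2
#' @export
teer <- function(r_meas, r_blank, m_area) {
  if (!is.numeric(m_area) || any(m_area <= 0))
    stop_domain("m_area", "must be > 0 cm^2")
  if (any(r_meas < 0) || any(r_blank < 0))
    stop_domain("resistance", "must be >= 0 Ohm")
  r_cells <- r_meas - r_blank
  if (any(r_cells < 0))
    warning("negative cell-layer resistance (measurement below blank) in ",
            sum(r_cells < 0), " record(s)", call. = FALSE)
  r_cells * m_area
}

#' Clearance-based filtration of a solute across the membrane
#'
#' Renal-clearance form: Filtration = [A] * AV / [B], where [A] is the
#' solute concentration in the apical outflow, AV the apical volume
#' collected, and [B] the concentration in the basal outflow. The result is
#' a cleared volume in the units of `apical_volume`. Free filtration
#' ([A] = [B]) clears exactly the apical volume; perfect retention gives 0.
#'
#' @param conc_apical apical outflow concentration (>= 0; vectorized).
#' @param apical_volume apical volume collected (> 0).
#' @param conc_basal basal outflow concentration (> 0), same unit as
#'   `conc_apical`.
#' @return Filtered (cleared) volume.
#' @examples
#' filtration(0.5, 120, 2) # 30
#' @export
filtration <- function(conc_apical, apical_volume, conc_basal) {
  if (any(conc_apical < 0))
    stop_domain("conc_apical", "must be >= 0")
  if (any(apical_volume <= 0))
    stop_domain("apical_volume", "must be > 0")
  if (any(conc_basal <= 0))
    stop_domain("conc_basal", "must be > 0 for a computable filtration")
  conc_apical * apical_volume / conc_basal
}

#' Filtration normalized to a blank membrane
#'
#' Ratio of the filtration with cells to the filtration observed on a blank
#' membrane without cells. 1 = no barrier beyond the membrane itself,
#' 0 = perfect barrier.
#'
#' @param f_cells filtered amount with cells (vectorized).
#' @param f_blank filtered amount on the blank membrane (> 0).
#' @return Dimensionless ratio.
#' @export
normalized_filtration <- function(f_cells, f_blank) {
  if (any(f_blank <= 0))
    stop_domain("f_blank", "must be > 0")
  f_cells / f_blank
}

#' Linear signal-to-concentration calibration
#'
#' Maps a raw plate-reader / spectrophotometer signal (absorbance or
#' fluorescence) onto concentration through a linear curve with blank
#' subtraction: conc = (signal - blank_signal - intercept) / slope, clamped
#' at 0. Clamped values are flagged through the `"clamped"` attribute and a
#' warning.
#'
#' @param mode `"absorbance_280nm"` or `"fluorescence"` (label only).
#' @param slope signal per concentration unit (> 0).
#' @param intercept signal offset after blank subtraction.
#' @param blank_signal signal of the blank well.
#' @return `calibration_curve()`: a `calibration_curve` object.
#' @export
calibration_curve <- function(slope, intercept = 0, blank_signal = 0,
                              mode = c("absorbance_280nm", "fluorescence")) {
  mode <- match.arg(mode)
  if (!is.numeric(slope) || length(slope) != 1L || slope <= 0)
    stop("calibration slope must be > 0", call. = FALSE)
  structure(list(mode = mode, slope = slope, intercept = intercept,
                 blank_signal = blank_signal), class = "calibration_curve")
}

#' @rdname calibration_curve
#' @param signal raw reading(s).
#' @param curve a `calibration_curve`.
#' @return `signal_to_concentration()`: concentration(s), with attribute
#'   `clamped` (logical vector).
#' @export
signal_to_concentration <- function(signal, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  conc <- (signal - curve$blank_signal - curve$intercept) / curve$slope
  clamped <- conc < 0
  if (any(clamped))
    warning(sum(clamped), " concentration(s) below zero clamped to 0",
            call. = FALSE)
  structure(pmax(conc, 0), clamped = clamped)
}

#' Batch filtration analysis over a readout table
#'
#' Computes per-row filtration, normalizes each (solute, condition) against
#' the mean filtration of that solute's blank rows, and returns a tidy
#' per-condition table ordered by (solute, condition). Blank rows normalize
#' to exactly 1 by construction.
#'
#' @param readouts data.frame with columns `solute`, `condition`,
#'   `conc_apical`, `apical_volume_ul`, `conc_basal`; blank-membrane rows
#'   carry `condition == blank_label`. Replicate rows are averaged.
#' @param blank_label condition label identifying blank-membrane rows.
#' @return data.frame `solute`, `condition`, `n`, `filtration_ul`,
#'   `filtration_sd`, `normalized_filtration` (empty input gives an empty
#'   table, no error).
#' @export
batch_assay <- function(readouts, blank_label = "blank") {
  stopifnot(is.data.frame(readouts))
  need <- c("solute", "condition", "conc_apical", "apical_volume_ul",
            "conc_basal")
  missing_cols <- setdiff(need, names(readouts))
  if (length(missing_cols))
    stop("readout table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  empty <- data.frame(solute = character(), condition = character(),
                      n = integer(), filtration_ul = numeric(),
                      filtration_sd = numeric(),
                      normalized_filtration = numeric())
  if (nrow(readouts) == 0) return(empty)

  readouts$f <- filtration(readouts$conc_apical, readouts$apical_volume_ul,
                           readouts$conc_basal)
  for (sol in unique(readouts$solute)) {
    if (!any(readouts$solute == sol & readouts$condition == blank_label))
      stop("no blank readout for solute '", sol,
           "': cannot normalize", call. = FALSE)
  }
  agg <- do.call(rbind, lapply(
    split(readouts, readouts[c("condition", "solute")], drop = TRUE),
    function(g) data.frame(solute = g$solute[1], condition = g$condition[1],
                           n = nrow(g), filtration_ul = mean(g$f),
                           filtration_sd = stats::sd(g$f))))
  blanks <- agg[agg$condition == blank_label, ]
  f_blank <- stats::setNames(blanks$filtration_ul, blanks$solute)
  agg$normalized_filtration <-
    normalized_filtration(agg$filtration_ul, f_blank[agg$solute])
  agg <- agg[order(agg$solute, agg$condition), ]
  rownames(agg) <- NULL
  agg
}
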