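#' Pneumatic pump pressure programs
#'
#' Idealized time-stamped pressure commands for the pneumatic pumps driving
#' the apical and basal channels: constants for steady perfusion, sinusoids
#' for breathing-cycle stretch (e.g. 345 mbar amplitude at 0.33 Hz = 20
#' breaths/min). Pump actuation dynamics are not modeled; the realized
#' pressure profile of a real pump will differ from the command.
#'
#' Pressures are commanded in mbar and must stay >= 0 (the pumps cannot pull
#' vacuum); a sinusoid whose trough would go negative is rejected unless
#' `clip = TRUE`, which clamps samples at 0.
#'
#' @param amplitude sine amplitude, mbar (>= 0).
#' @param frequency sine frequency, Hz (> 0).
#' @param offset baseline pressure, mbar.
#' @param pressure constant pressure, mbar (>= 0).
#' @param duration program duration, s (> 0).
#' @param sample_rate samples per second (default 10 Hz); sampling is
#'   inclusive of the endpoint, so a program holds
#'   `duration * sample_rate + 1` samples.
#' @param channel `"apical"` or `"basal"`.
#' @param clip clamp negative commanded pressures to 0 instead of erroring.
#' @return A `pump_program`: data.frame `time_s`, `pressure_mbar` with
#'   attributes `channel` and `sample_rate`.
#' @name pump-programs
NULL

new_pump_program <- function(time_s, pressure_mbar, channel, sample_rate) {
  channel <- match.arg(channel, c("apical", "basal"))
  if (any(pressure_mbar < 0))
    stop("pump pressures must be >= 0 mbar (use clip = TRUE to clamp)",
         call. = FALSE)
  if (is.unsorted(time_s, strictly = TRUE))
    stop("program times must be strictly increasing", call. = FALSE)
  structure(data.frame(time_s = time_s, pressure_mbar = pressure_mbar),
            channel = channel, sample_rate = sample_rate,
            class = c("pump_program", "data.frame"))
}

#' @rdname pump-programs
#' @export
sine_program <- function(amplitude, frequency, offset, duration,
                         sample_rate = 10, channel = "apical",
                         clip = FALSE) {
  stopifnot(amplitude >= 0, frequency > 0, duration > 0, sample_rate > 0)
  if (!clip && offset < amplitude)
    stop("offset must be >= amplitude so pressures stay >= 0 ",
         "(or enable clip)", call. = FALSE)
  i <- 0:round(duration * sample_rate)
  t <- i / sample_rate
  p <- offset + amplitude * sin(2 * pi * frequency * t)
  if (clip) p <- pmax(p, 0)
  new_pump_program(t, p, channel, sample_rate)
}

#' @rdname pump-programs
#' @export
constant_program <- function(pressure, duration, sample_rate = 10,
                             channel = "basal") {
  stopifnot(pressure >= 0, sample_rate > 0)
  if (duration <= 0) stop("duration must be > 0", call. = FALSE)
  i <- 0:round(duration * sample_rate)
  new_pump_program(i / sample_rate, rep(pressure, length(i)), channel,
                   sample_rate)
}

#' @export
print.pump_program <- function(x, ...) {
  cat(sprintf(
    "<pump_program> %s channel, %d samples @ %g Hz, %.4g-%.4g mbar\n",
    attr(x, "channel"), nrow(x), attr(x, "sample_rate"),
    min(x$pressure_mbar), max(x$pressure_mbar)))
  invisible(x)
}

#' Export / import pump programs as CSV
#'
#' Deterministic fixed-decimal formatting (6 decimal places) so that an
#' exported program re-imports and re-exports byte-identically.
#'
#' @param program a `pump_program`.
#' @param path CSV file path.
#' @return `write_pump_program()` returns `path` invisibly;
#'   `read_pump_program()` returns a `pump_program`.
#' @export
write_pump_program <- function(program, path) {
  stopifnot(inherits(program, "pump_program"))
  con <- file(path, open = "wb") # binary: fixed \n on every platform
  on.exit(close(con))
  writeLines(c(
    sprintf("# channel=%s sample_rate=%.6f", attr(program, "channel"),
            attr(program, "sample_rate")),
    "time_s,pressure_mbar",
    sprintf("%.6f,%.6f", program$time_s, program$pressure_mbar)),
    con, sep = "\n")
  invisible(path)
}

#' @rdname write_pump_program
#' @export
read_pump_program <- function(path) {
  header <- readLines(path, n = 1)
  meta <- regmatches(header,
                     regexec("channel=(\\w+) sample_rate=([0-9.]+)", header))[[1]]
  if (length(meta) != 3) stop("not a pump program CSV: ", path, call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#")
  new_pump_program(df$time_s, df$pressure_mbar, meta[2], as.numeric(meta[3]))
}
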