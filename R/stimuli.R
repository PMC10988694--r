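#' Ramp-hold-release stretch specification
#'
#' Defines a piecewise-linear length-controlled stretch: a baseline at
#' resting length, a constant-velocity ramp to `amplitude_mm`, a hold
#' plateau, a constant-velocity release back to resting length, and a
#' post-release tail.  Lengths are displacements from resting length (mm).
#'
#' @param baseline_s Pre-stretch duration in seconds.
#' @param amplitude_mm Stretch amplitude in mm (>= 0).
#' @param velocity_mm_per_s Ramp and release speed in mm/s (> 0).
#'   The default 20 mm/s is the classical identification ramp speed for
#'   Ia afferents.
#' @param hold_s Plateau duration in seconds.
#' @param post_s Post-release duration in seconds.
#' @param dt_s Sample step in seconds (> 0).
#' @return An object of class `ramp_spec`.
#' @export
ramp_spec <- function(baseline_s = 0.2, amplitude_mm = 3,
                      velocity_mm_per_s = 20, hold_s = 1,
                      post_s = 0.2, dt_s = 1e-4) {
  stopifnot(is.numeric(amplitude_mm), is.numeric(velocity_mm_per_s))
  if (amplitude_mm < 0) stop("amplitude_mm must be >= 0")
  if (velocity_mm_per_s <= 0) stop("velocity_mm_per_s must be > 0")
  if (dt_s <= 0) stop("dt_s must be > 0")
  if (baseline_s < 0 || hold_s < 0 || post_s < 0)
    stop("durations must be >= 0")
  structure(list(baseline_s = baseline_s, amplitude_mm = amplitude_mm,
                 velocity_mm_per_s = velocity_mm_per_s, hold_s = hold_s,
                 post_s = post_s, dt_s = dt_s),
            class = "ramp_spec")
}

new_stimulus <- function(t, length_mm, label = "stimulus") {
  stopifnot(length(t) == length(length_mm), length(t) >= 2)
  if (any(!is.finite(length_mm))) stop("length trace must be finite")
  dt <- diff(t)
  if (any(dt <= 0)) stop("time grid must be strictly increasing")
  if (diff(range(dt)) > 1e-9 * max(dt))
    stop("time grid must have a constant step")
  structure(list(t = as.numeric(t), length_mm = as.numeric(length_mm),
                 dt_s = mean(dt), label = label),
            class = "stretch_stimulus")
}

#' @export
print.stretch_stimulus <- function(x, ...) {
  cat(sprintf("<stretch_stimulus '%s': %d samples, dt = %g s, %.3f s, peak %.3g mm>\n",
              x$label, length(x$t), x$dt_s, max(x$t), max(abs(x$length_mm))))
  invisible(x)
}

#' Generate a ramp-hold-release stretch stimulus
#'
#' @param spec A [ramp_spec()].
#' @return A `stretch_stimulus` with fields `t` (s), `length_mm`
#'   (displacement from resting length) and `dt_s`.
#' @examples
#' stim <- make_ramp_hold_release(ramp_spec(amplitude_mm = 3))
#' max(stim$length_mm)  # 3
#' @export
make_ramp_hold_release <- function(spec = ramp_spec()) {
  stopifnot(inherits(spec, "ramp_spec"))
  ramp_s <- spec$amplitude_mm / spec$velocity_mm_per_s
  total <- spec$baseline_s + 2 * ramp_s + spec$hold_s + spec$post_s
  n <- max(2L, floor(total / spec$dt_s) + 1L)
  t <- seq(0, by = spec$dt_s, length.out = n)
  t1 <- spec$baseline_s            # ramp on
  t2 <- t1 + ramp_s                # hold start
  t3 <- t2 + spec$hold_s           # release start
  t4 <- t3 + ramp_s                # release end
  len <- numeric(n)
  up <- t >= t1 & t < t2
  len[up] <- spec$velocity_mm_per_s * (t[up] - t1)
  len[t >= t2 & t < t3] <- spec$amplitude_mm
  dn <- t >= t3 & t < t4
  len[dn] <- spec$amplitude_mm - spec$velocity_mm_per_s * (t[dn] - t3)
  new_stimulus(t, len, label = sprintf("ramp_%gmm_%gmmps", spec$amplitude_mm,
                                       spec$velocity_mm_per_s))
}

#' Generate a sinusoidal (vibration) stretch stimulus
#'
#' Zero-mean sinusoidal length perturbation, e.g. the 100 Hz / 80 um
#' vibration used to identify Ia afferents.
#'
#' @param freq_hz Vibration frequency in Hz (> 0).
#' @param amplitude_mm Peak amplitude in mm.
#' @param duration_s Total duration in seconds.
#' @param dt_s Sample step; must satisfy the Nyquist bound
#'   `dt_s < 1/(2 * freq_hz)`.
#' @return A `stretch_stimulus`.
#' @export
make_sinusoid <- function(freq_hz = 100, amplitude_mm = 0.08,
                          duration_s = 1, dt_s = 1e-4) {
  if (freq_hz <= 0) stop("freq_hz must be > 0")
  if (dt_s <= 0) stop("dt_s must be > 0")
  if (dt_s >= 1 / (2 * freq_hz))
    stop("dt_s undersamples the requested frequency (Nyquist)")
  n <- max(2L, floor(duration_s / dt_s) + 1L)
  t <- seq(0, by = dt_s, length.out = n)
  new_stimulus(t, amplitude_mm * sin(2 * pi * freq_hz * t),
               label = sprintf("sine_%gHz_%gmm", freq_hz, amplitude_mm))
}

#' Read a stretch stimulus from a two-column table
#'
#' Reads a CSV with columns `t_s,length_mm` (header optional).  Non-uniform
#' time grids are resampled to a uniform step by linear interpolation; the
#' endpoints are preserved.
#'
#' @param source Path to a CSV file, or a data frame with two numeric
#'   columns (time in s, length in mm).
#' @param dt_s Target step for resampling non-uniform input; `NULL` keeps
#'   the input step when it is already uniform, otherwise uses the median
#'   input step.
#' @return A `stretch_stimulus`.
#' @export
read_stimulus_table <- function(source, dt_s = NULL) {
  if (is.character(source)) {
    first <- readLines(source, n = 1L)
    has_header <- grepl("[A-Za-z]", first)
    df <- utils::read.csv(source, header = has_header)
  } else {
    df <- as.data.frame(source)
  }
  if (ncol(df) < 2L) stop("stimulus table needs two columns (t_s, length_mm)")
  t <- as.numeric(df[[1L]]); len <- as.numeric(df[[2L]])
  if (length(t) < 2L) stop("stimulus table needs at least 2 rows")
  if (any(!is.finite(t)) || any(!is.finite(len)))
    stop("stimulus table contains non-finite values")
  if (any(diff(t) <= 0)) stop("time column must be strictly increasing")
  steps <- diff(t)
  uniform <- diff(range(steps)) <= 1e-9 * max(steps)
  if (uniform && is.null(dt_s)) return(new_stimulus(t, len, "from_table"))
  if (is.null(dt_s)) dt_s <- stats::median(steps)
  tg <- seq(t[1L], t[length(t)], by = dt_s)
  if (tg[length(tg)] < t[length(t)] - 1e-12) tg <- c(tg, t[length(t)])
  # a trailing partial step would break the uniform-grid invariant
  if (length(tg) >= 2L && diff(range(diff(tg))) > 1e-9 * dt_s)
    tg <- seq(t[1L], by = dt_s, length.out = length(tg))
  lg <- stats::approx(t, len, xout = tg, rule = 2)$y
  new_stimulus(tg, lg, "from_table")
}

#' Write a stretch stimulus to CSV
#'
#' @param stim A `stretch_stimulus`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stimulus_table <- function(stim, path) {
  stopifnot(inherits(stim, "stretch_stimulus"))
  utils::write.csv(data.frame(t_s = stim$t, length_mm = stim$length_mm),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Phase boundaries of a ramp-hold-release stimulus
#'
#' @param spec A [ramp_spec()].
#' @return List with times (s) of ramp onset, hold start, release start and
#'   release end.
#' @export
stimulus_phases <- function(spec) {
  stopifnot(inherits(spec, "ramp_spec"))
  ramp_s <- spec$amplitude_mm / spec$velocity_mm_per_s
  list(ramp_on = spec$baseline_s,
       hold_on = spec$baseline_s + ramp_s,
       release_on = spec$baseline_s + ramp_s + spec$hold_s,
       release_off = spec$baseline_s + 2 * ramp_s + spec$hold_s)
}
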