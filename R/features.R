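#' Detect spikes by threshold crossing
#'
#' Upward threshold crossings with a refractory rule; spike times are
#' linearly interpolated between samples.
#'
#' @param t Time grid (s), uniform.
#' @param V Voltage trace (mV).
#' @param threshold_mV Crossing threshold.
#' @param min_isi_ms Minimum inter-spike interval; later crossings inside
#'   this window are discarded.
#' @return A `spike_train` list with `times` (s).
#' @export
detect_spikes <- function(t, V, threshold_mV = -20, min_isi_ms = 1) {
  stopifnot(length(t) == length(V))
  up <- which(V[-1] >= threshold_mV & V[-length(V)] < threshold_mV)
  times <- numeric(0)
  if (length(up)) {
    frac <- (threshold_mV - V[up]) / (V[up + 1] - V[up])
    times <- t[up] + frac * (t[up + 1] - t[up])
    keep <- logical(length(times))
    last <- -Inf
    for (i in seq_along(times)) {
      if (times[i] - last >= min_isi_ms * 1e-3) {
        keep[i] <- TRUE
        last <- times[i]
      }
    }
    times <- times[keep]
  }
  structure(list(times = times), class = "spike_train")
}

#' Instantaneous firing rate of a spike train
#'
#' `IFR_i = 1/(t_i - t_{i-1})`, assigned at `t_i`.
#'
#' @param s A `spike_train` (or numeric vector of spike times in s).
#' @return Data frame with `t` (s) and `pps`; empty for fewer than two
#'   spikes.
#' @export
instantaneous_rate <- function(s) {
  times <- if (inherits(s, "spike_train")) s$times else as.numeric(s)
  if (length(times) < 2)
    return(data.frame(t = numeric(0), pps = numeric(0)))
  isi <- diff(times)
  data.frame(t = times[-1], pps = 1 / isi)
}

#' Feature-window definitions for a ramp-hold-release stimulus
#'
#' @param spec The [ramp_spec()] behind the stimulus.
#' @param onset_window_s Width of the initial-burst window after ramp
#'   onset.
#' @param static_fraction Central fraction of the hold phase used for the
#'   static average.
#' @return List of `c(start, end)` windows (s) for `burst`, `dynamic`
#'   and `static`.
#' @export
feature_windows <- function(spec, onset_window_s = 0.1,
                            static_fraction = 0.8) {
  ph <- stimulus_phases(spec)
  hold <- ph$release_on - ph$hold_on
  pad <- hold * (1 - static_fraction) / 2
  list(burst = c(ph$ramp_on, ph$ramp_on + onset_window_s),
       dynamic = c(ph$ramp_on, ph$hold_on),
       static = c(ph$hold_on + pad, ph$release_on - pad))
}

#' Extract the three headline Ia encoding features
#'
#' Initial burst = maximum instantaneous firing rate (IFR) within the
#' onset window; peak dynamic = maximum IFR during the ramp; static
#' average = mean IFR over the central portion of the hold plateau.  A
#' window containing no IFR samples yields a 0 feature and a flag
#' (`"static failure"` for the static window -- the phenotype where
#' static firing ceases entirely).
#'
#' @param s A `spike_train`.
#' @param spec The [ramp_spec()] of the stimulus.
#' @param windows Optional window list from [feature_windows()].
#' @return A `firing_features` list: `initial_burst_pps`,
#'   `peak_dynamic_pps`, `static_avg_pps`, `flags`, `windows`.
#' @export
extract_features <- function(s, spec, windows = feature_windows(spec)) {
  ifr <- instantaneous_rate(s)
  flags <- character(0)
  in_win <- function(w) ifr$pps[ifr$t > w[1] & ifr$t <= w[2]]
  bw <- in_win(windows$burst)
  dw <- in_win(windows$dynamic)
  sw <- in_win(windows$static)
  burst <- if (length(bw)) max(bw) else {
    flags <- c(flags, "burst failure"); 0
  }
  dyn <- if (length(dw)) max(dw) else {
    flags <- c(flags, "dynamic failure"); 0
  }
  stat <- if (length(sw)) mean(sw) else {
    flags <- c(flags, "static failure"); 0
  }
  structure(list(initial_burst_pps = burst, peak_dynamic_pps = dyn,
                 static_avg_pps = stat, flags = flags, windows = windows),
            class = "firing_features")
}

#' @export
print.firing_features <- function(x, ...) {
  cat(sprintf(
    "<firing_features: burst %.1f pps, peak dynamic %.1f pps, static %.1f pps%s>\n",
    x$initial_burst_pps, x$peak_dynamic_pps, x$static_avg_pps,
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = "; "), "]")
    else ""))
  invisible(x)
}

#' Percent change relative to a base value
#'
#' Uses the reduction-positive convention: `100 * (base - test) / base`,
#' so a drop from 100 to 72.3 is reported as +27.7%.
#'
#' @param test Perturbed value.
#' @param base Reference value (> 0).
#' @return Percent change.
#' @export
percent_change <- function(test, base) {
  if (base <= 0) stop("percent_change is undefined for base <= 0")
  100 * (base - test) / base
}
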