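# Surface-EMG and force operators used in the fatigue and co-contraction
# analyses: RMS envelope, area under the envelope, the antagonist/agonist
# co-contraction ratio, the equal-power median frequency (MDF), windowed
# fatigue-onset detectors, peak volitional force and the injured-vs-
# uninjured percentage difference.

#' Surface-EMG recording
#'
#' @param samples Numeric vector of raw EMG samples (mV), uniformly sampled.
#' @param sampling_rate Sampling rate in Hz.
#' @param role Channel role: `"agonist"` (elbow flexors) or `"antagonist"`
#'   (extensors).
#' @param condition `"uninjured"` or `"injured"` arm.
#' @return An `emg_recording` object.
#' @export
emg_recording <- function(samples, sampling_rate,
                          role = c("agonist", "antagonist"),
                          condition = c("uninjured", "injured")) {
  role <- match.arg(role)
  condition <- match.arg(condition)
  if (length(samples) == 0L || any(!is.finite(samples))) {
    stop_input("samples must be a non-empty finite numeric vector")
  }
  check_scalar_number(sampling_rate, "sampling_rate", 0, strict_lower = TRUE)
  structure(
    list(samples = as.numeric(samples), sampling_rate = sampling_rate,
         role = role, condition = condition),
    class = "emg_recording"
  )
}

#' Force trace
#'
#' @param samples Numeric vector of force samples (KgF), uniformly sampled.
#' @param sampling_rate Sampling rate in Hz.
#' @param condition `"uninjured"` or `"injured"` arm.
#' @return A `force_trace` object.
#' @export
force_trace <- function(samples, sampling_rate,
                        condition = c("uninjured", "injured")) {
  condition <- match.arg(condition)
  if (length(samples) == 0L || any(!is.finite(samples))) {
    stop_input("samples must be a non-empty finite numeric vector")
  }
  check_scalar_number(sampling_rate, "sampling_rate", 0, strict_lower = TRUE)
  structure(
    list(samples = as.numeric(samples), sampling_rate = sampling_rate,
         condition = condition),
    class = "force_trace"
  )
}

fatigue_result <- function(baseline_value, onset_time_s, censored, method) {
  structure(
    list(baseline_value = baseline_value, onset_time_s = onset_time_s,
         censored = censored, method = method),
    class = "fatigue_result"
  )
}

#' @export
print.fatigue_result <- function(x, ...) {
  onset <- if (x$censored) "censored (threshold never crossed)" else
    sprintf("%.2f s", x$onset_time_s)
  cat(sprintf("Fatigue onset (%s): baseline %.2f, onset %s\n",
              x$method, x$baseline_value, onset))
  invisible(x)
}

# centred moving sum with shrinking edge windows, via cumulative sums
moving_stat_centered <- function(x, width) {
  n <- length(x)
  half_lo <- floor((width - 1) / 2)
  half_hi <- width - 1L - half_lo
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - half_lo, 1L)
  hi <- pmin(seq_len(n) + half_hi, n)
  list(sum = cs[hi + 1L] - cs[lo], n = hi - lo + 1L)
}

#' RMS envelope of an EMG signal
#'
#' Sliding-window root mean square on the input's own time base (window
#' centre convention); windows shrink at the record edges.
#'
#' @param rec An [emg_recording()] or numeric vector.
#' @param window_s Window length in seconds; `window_s * sampling_rate` must
#'   be at least 1 sample.
#' @param sampling_rate Required when `rec` is a bare numeric vector.
#' @return Numeric vector of RMS values, same length as the input.
#' @export
rms_envelope <- function(rec, window_s = 0.5, sampling_rate = NULL) {
  if (inherits(rec, "emg_recording")) {
    x <- rec$samples
    fs <- rec$sampling_rate
  } else {
    x <- as.numeric(rec)
    fs <- sampling_rate
    if (is.null(fs)) stop_input("sampling_rate required for a bare vector")
  }
  if (length(x) == 0L) stop_input("empty signal")
  width <- round(window_s * fs)
  if (width < 1) stop_input("window_s * sampling_rate must be >= 1")
  ms <- moving_stat_centered(x^2, width)
  sqrt(ms$sum / ms$n)
}

#' Area under an envelope curve
#'
#' Trapezoidal integral of the envelope over the full record (mV s for an
#' RMS envelope in mV).
#'
#' @param envelope Numeric vector (at least 2 points).
#' @param sampling_rate Sampling rate in Hz.
#' @return Scalar integral.
#' @export
area_under_curve <- function(envelope, sampling_rate) {
  if (length(envelope) < 2L) stop_input("envelope must have at least 2 points")
  check_scalar_number(sampling_rate, "sampling_rate", 0, strict_lower = TRUE)
  tt <- (seq_along(envelope) - 1) / sampling_rate
  pracma::trapz(tt, envelope)
}

#' Co-contraction ratio around the elbow joint
#'
#' Area under the antagonist (triceps) RMS envelope divided by the area
#' under the agonist (biceps) envelope during the agonist's sustained
#' isometric contraction. Healthy arms sit near 0.12; chronically
#' reinnervated arms near 0.26.
#'
#' @param antagonist_aoc,agonist_aoc Areas under the two RMS envelopes
#'   (mV s); the agonist area must be positive.
#' @return Dimensionless ratio.
#' @export
cocontraction_ratio <- function(antagonist_aoc, agonist_aoc) {
  if (any(!is.finite(agonist_aoc)) || any(agonist_aoc <= 0)) {
    stop_input("agonist_aoc must be positive (silent agonist gives an undefined ratio)")
  }
  antagonist_aoc / agonist_aoc
}

#' Equal-power median frequency of an EMG segment
#'
#' The frequency that splits the periodogram into two halves of equal
#' integrated power. Each discrete spectral bin is treated as a uniform
#' density over its own frequency interval, so the half-power point is
#' linearly interpolated inside the bin where it falls; a pure tone returns
#' its own frequency.
#'
#' @param segment An [emg_recording()] or numeric vector (>= 2 samples).
#' @param sampling_rate Required for a bare numeric vector.
#' @return Median frequency in Hz.
#' @export
median_frequency <- function(segment, sampling_rate = NULL) {
  if (inherits(segment, "emg_recording")) {
    x <- segment$samples
    fs <- segment$sampling_rate
  } else {
    x <- as.numeric(segment)
    fs <- sampling_rate
    if (is.null(fs)) stop_input("sampling_rate required for a bare vector")
  }
  n <- length(x)
  if (n < 2L) stop_input("segment must have at least 2 samples")
  spec <- Mod(stats::fft(x))^2
  n_half <- floor(n / 2) + 1L
  power <- spec[seq_len(n_half)]
  # fold the redundant half onto the one-sided spectrum
  if (n > 2L) {
    upper <- spec[seq.int(n, n_half + 1L)]
    k <- seq_along(upper) + 1L
    power[k] <- power[k] + upper
  }
  total <- sum(power)
  if (total <= 0 || !is.finite(total)) stop_input("segment has zero power; MDF undefined")
  df <- fs / n
  freqs <- (seq_len(n_half) - 1L) * df
  cum <- cumsum(power)
  half <- total / 2
  k <- which(cum >= half)[1L]
  prev <- if (k == 1L) 0 else cum[k - 1L]
  # bin k spans [freqs[k] - df/2, freqs[k] + df/2]
  f_star <- freqs[k] - df / 2 + df * (half - prev) / power[k]
  max(f_star, 0)
}

# per-window statistic on consecutive non-overlapping windows; returns the
# window start times alongside the values
window_series <- function(x, fs, window_s, stat) {
  width <- round(window_s * fs)
  n_win <- floor(length(x) / width)
  starts <- (seq_len(n_win) - 1L) * width
  vals <- vapply(seq_len(n_win), function(i) {
    stat(x[(starts[i] + 1L):(starts[i] + width)])
  }, numeric(1))
  list(start_s = starts / fs, value = vals)
}

onset_from_series <- function(series, baseline_window_s, threshold_frac,
                              persistence, baseline_stat = mean) {
  in_baseline <- series$start_s < baseline_window_s
  if (!any(in_baseline)) stop_input("record shorter than the baseline window")
  baseline <- baseline_stat(series$value[in_baseline])
  candidates <- which(!in_baseline & series$value < threshold_frac * baseline)
  onset <- NA_real_
  if (length(candidates) > 0 && persistence > 1) {
    runs <- split(candidates, cumsum(c(1, diff(candidates) != 1)))
    ok <- vapply(runs, function(r) length(r) >= persistence, logical(1))
    candidates <- if (any(ok)) runs[[which(ok)[1L]]] else integer(0)
  }
  if (length(candidates) > 0) onset <- series$start_s[candidates[1L]]
  list(baseline = baseline, onset = onset, censored = is.na(onset))
}

#' Fatigue onset from median-frequency decline
#'
#' The baseline is the mean of per-window MDFs over the first 10 s of the
#' sustained contraction; fatigue onset is the start time of the first
#' analysis window (at or after 10 s) whose MDF has fallen by more than 10%
#' from that baseline. If the threshold is never crossed the result is
#' censored.
#'
#' @param rec An [emg_recording()] of at least 10 s.
#' @param window_s MDF analysis window in seconds (default 1, non-overlapping).
#' @param drop_frac Fractional MDF drop defining onset (default 0.10).
#' @param persistence Number of consecutive sub-threshold windows required
#'   (default 1, i.e. first crossing).
#' @return A `fatigue_result` with the baseline MDF (Hz) and onset time (s).
#' @export
mdf_fatigue_onset <- function(rec, window_s = 1, drop_frac = 0.10,
                              persistence = 1L) {
  if (!inherits(rec, "emg_recording")) stop_input("rec must be an emg_recording")
  dur <- length(rec$samples) / rec$sampling_rate
  if (dur < 10) stop_input("record must be at least 10 s for the baseline window")
  series <- window_series(rec$samples, rec$sampling_rate, window_s,
                          function(w) median_frequency(w, rec$sampling_rate))
  res <- onset_from_series(series, 10, 1 - drop_frac, persistence)
  fatigue_result(res$baseline, res$onset, res$censored, "mdf")
}

#' Fatigue onset from force decline
#'
#' The baseline is the mean force over the first 10 s; onset is the start
#' time of the first analysis window (at or after 10 s) whose mean force
#' falls below 50% of that baseline; censored if never crossed.
#'
#' @param trace A [force_trace()] of at least 10 s.
#' @param window_s Averaging window in seconds (default 1, non-overlapping).
#' @param drop_frac Fractional force drop defining onset (default 0.50).
#' @param persistence Consecutive sub-threshold windows required (default 1).
#' @return A `fatigue_result` with baseline force (KgF) and onset time (s).
#' @export
force_fatigue_onset <- function(trace, window_s = 1, drop_frac = 0.50,
                                persistence = 1L) {
  if (!inherits(trace, "force_trace")) stop_input("trace must be a force_trace")
  fs <- trace$sampling_rate
  dur <- length(trace$samples) / fs
  if (dur < 10) stop_input("trace must be at least 10 s for the baseline window")
  series <- window_series(trace$samples, fs, window_s, mean)
  # baseline is the mean of the raw first-10-s force, not of window means of
  # unequal length; with equal windows the two agree exactly
  baseline <- mean(trace$samples[seq_len(floor(10 * fs))])
  res <- onset_from_series(series, 10, 1 - drop_frac, persistence,
                           baseline_stat = function(v) baseline)
  fatigue_result(baseline, res$onset, res$censored, "force")
}

#' Peak volitional force over repeated contractions
#'
#' Maximum force sample across a set of repeated maximal isometric
#' contractions (the protocol uses ten).
#'
#' @param traces A [force_trace()] or list of them.
#' @return Peak force in KgF.
#' @export
peak_volitional_force <- function(traces) {
  if (inherits(traces, "force_trace")) traces <- list(traces)
  if (length(traces) == 0L) stop_input("at least one force trace required")
  max(vapply(traces, function(tr) {
    if (!inherits(tr, "force_trace")) stop_input("traces must be force_trace objects")
    max(tr$samples)
  }, numeric(1)))
}

#' Percentage difference between injured and uninjured arms
#'
#' `100 * (uninjured - injured) / uninjured`: positive values mean the
#' injured arm performs worse (shorter time to fatigue, lower force).
#'
#' @param injured_value,uninjured_value Paired measurements; the uninjured
#'   value must be positive.
#' @return Percentage difference.
#' @export
percent_difference <- function(injured_value, uninjured_value) {
  if (any(!is.finite(uninjured_value)) || any(uninjured_value <= 0)) {
    stop_input("uninjured_value must be positive")
  }
  100 * (uninjured_value - injured_value) / uninjured_value
}
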