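# Synthetic surface-EMG and force signals.
#
# The agonist channel is band-limited Gaussian noise synthesised per 1-s
# block in the frequency domain: a flat band [f_lo, 2*m - f_lo] has
# equal-power median frequency m, so the block's target MDF is controlled
# directly and declines linearly over the contraction ("spectral
# compression" with fatigue). The antagonist is independent noise whose RMS
# is a configured fraction of the agonist RMS, so the co-contraction ratio
# has that fraction as its expectation. The force trace is an exponential
# decay whose 50%-of-baseline crossing time is set analytically.

#' Simulation parameters for sEMG and force recordings
#'
#' Defaults are calibrated to the published group statistics for sustained
#' isometric elbow flexion: baseline MDF (mean over the first 10 s)
#' 73.13 Hz (uninjured) / 62.90 Hz (injured), co-contraction ratios
#' 0.12 / 0.26, 50%-force-drop times 39.12 s / 32.21 s, and peak forces
#' 31.51 / 12.55 KgF. The per-window MDF declines linearly at rate `r` from
#' an initial value `m0 = baseline + 5 r` (so the first-10-s mean equals
#' the configured baseline); the >10% drop from baseline is then crossed at
#' `t = 0.1 baseline / r + 5`, and the default decay rates place that
#' crossing at the published mean onsets of 32.10 s (uninjured) and
#' 22.84 s (injured).
#'
#' @param sampling_rate Sampling rate in Hz (default 1000).
#' @param duration Contraction length in seconds (>= 10 s; default 60, long
#'   enough that right-censoring of the simulated fatigue onsets is rare).
#' @param baseline_mdf Named vector, mean MDF over the first 10 s (Hz) by
#'   condition.
#' @param baseline_mdf_sd Named vector, between-recording SD of the
#'   baseline MDF (Hz).
#' @param mdf_decay_rate Named vector, linear MDF decline (Hz/s).
#' @param f_low Lower edge of the EMG band (Hz).
#' @param agonist_amplitude Agonist RMS amplitude (mV).
#' @param cocontraction_ratio_target Named vector, mean antagonist/agonist
#'   ratio by condition.
#' @param cocontraction_ratio_sd Named vector, between-recording SD of the
#'   ratio.
#' @param force_baseline Named vector, mean initial force (KgF).
#' @param force_baseline_sd Named vector, between-recording SD (KgF).
#' @param force_decay_halftime Named vector, time (s) at which force crosses
#'   50% of its first-10-s mean.
#' @param force_decay_halftime_sd Named vector, between-recording SD (s).
#' @param force_noise_sd Additive force noise SD (KgF).
#' @param subjective_onset_mean Named vector, mean reported subjective
#'   fatigue onset (s); an input datum in the analysis, generated here for
#'   completeness.
#' @param subjective_onset_sd Named vector, SD of the reported onset (s).
#' @return An `emg_sim_params` list.
#' @export
emg_sim_params <- function(sampling_rate = 1000,
                           duration = 60,
                           baseline_mdf = c(uninjured = 73.13, injured = 62.90),
                           baseline_mdf_sd = c(uninjured = 4.62, injured = 5.89),
                           mdf_decay_rate = c(uninjured = 0.270, injured = 0.353),
                           f_low = 20,
                           agonist_amplitude = 0.5,
                           cocontraction_ratio_target = c(uninjured = 0.12, injured = 0.26),
                           cocontraction_ratio_sd = c(uninjured = 0.06, injured = 0.09),
                           force_baseline = c(uninjured = 31.51, injured = 12.55),
                           force_baseline_sd = c(uninjured = 5.67, injured = 6.75),
                           force_decay_halftime = c(uninjured = 39.12, injured = 32.21),
                           force_decay_halftime_sd = c(uninjured = 8.26, injured = 7.14),
                           force_noise_sd = 0.05,
                           subjective_onset_mean = c(uninjured = 40.87, injured = 29.06),
                           subjective_onset_sd = c(uninjured = 13.62, injured = 6.32)) {
  check_scalar_number(sampling_rate, "sampling_rate", 0, strict_lower = TRUE)
  check_scalar_number(duration, "duration", 0, strict_lower = TRUE)
  check_scalar_number(f_low, "f_low", 0)
  check_scalar_number(agonist_amplitude, "agonist_amplitude", 0)
  check_scalar_number(force_noise_sd, "force_noise_sd", 0)
  for (nm in c("baseline_mdf", "baseline_mdf_sd", "mdf_decay_rate",
               "cocontraction_ratio_target", "cocontraction_ratio_sd",
               "force_baseline", "force_baseline_sd", "force_decay_halftime",
               "force_decay_halftime_sd", "subjective_onset_mean",
               "subjective_onset_sd")) {
    v <- get(nm)
    if (!all(c("uninjured", "injured") %in% names(v))) {
      stop_config(nm, " must be named with conditions uninjured and injured")
    }
    if (any(v < 0)) stop_config(nm, " must be non-negative")
  }
  if (sampling_rate <= 2 * (2 * max(baseline_mdf) - f_low)) {
    stop_config("sampling_rate must exceed twice the highest simulated frequency")
  }
  structure(
    list(
      sampling_rate = sampling_rate, duration = duration,
      baseline_mdf = baseline_mdf, baseline_mdf_sd = baseline_mdf_sd,
      mdf_decay_rate = mdf_decay_rate, f_low = f_low,
      agonist_amplitude = agonist_amplitude,
      cocontraction_ratio_target = cocontraction_ratio_target,
      cocontraction_ratio_sd = cocontraction_ratio_sd,
      force_baseline = force_baseline, force_baseline_sd = force_baseline_sd,
      force_decay_halftime = force_decay_halftime,
      force_decay_halftime_sd = force_decay_halftime_sd,
      force_noise_sd = force_noise_sd,
      subjective_onset_mean = subjective_onset_mean,
      subjective_onset_sd = subjective_onset_sd
    ),
    class = "emg_sim_params"
  )
}

# one block of flat-band noise on [f_lo, f_hi] with unit RMS, synthesised in
# the frequency domain with random phases; edge bins get fractional power
# proportional to their overlap with the band so the spectral edges (and
# hence the MDF) are not quantised to the bin grid
band_noise_block <- function(n, fs, f_lo, f_hi) {
  n_half <- floor(n / 2)
  df <- fs / n
  freqs <- (1:n_half) * df
  overlap <- pmin(f_hi, freqs + df / 2) - pmax(f_lo, freqs - df / 2)
  amp <- sqrt(pmax(overlap, 0) / df)
  phase <- stats::runif(n_half, 0, 2 * pi)
  half <- amp * exp(1i * phase)
  if (n %% 2 == 0) half[n_half] <- Re(half[n_half]) # Nyquist bin must be real
  spectrum <- c(0, half, Conj(rev(half[seq_len(n_half - (n %% 2 == 0))])))
  x <- Re(stats::fft(spectrum, inverse = TRUE)) / n
  rms <- sqrt(mean(x^2))
  if (rms > 0) x / rms else x
}

mdf_band_signal <- function(n_blocks, block_n, fs, f_lo, mdf_start,
                            decay_rate) {
  centres <- (seq_len(n_blocks) - 0.5) * block_n / fs
  target <- pmax(mdf_start - decay_rate * centres, f_lo + 5)
  unlist(lapply(seq_len(n_blocks), function(k) {
    band_noise_block(block_n, fs, f_lo, 2 * target[k] - f_lo)
  }), use.names = FALSE)
}

#' Simulate an agonist/antagonist EMG pair with a force trace
#'
#' Draws recording-level parameters (initial MDF, co-contraction ratio,
#' initial force and 50%-drop time) from the per-condition calibration, then
#' synthesises the three signals. The agonist's per-window MDF starts at the
#' drawn initial value and declines linearly; the antagonist is scaled so
#' the expected co-contraction ratio equals the drawn target (a target of
#' exactly 0 yields an identically zero channel); the force decays
#' exponentially through 50% of its first-10-s mean at the drawn crossing
#' time.
#'
#' @param params An [emg_sim_params()].
#' @param condition `"uninjured"` or `"injured"`.
#' @param seed Optional seed.
#' @return List with `agonist`, `antagonist` ([emg_recording()]), `force`
#'   ([force_trace()]), `subjective_onset_s`, and the drawn `true`
#'   parameters.
#' @export
generate_emg_pair <- function(params, condition = c("uninjured", "injured"),
                              seed = NULL) {
  if (!inherits(params, "emg_sim_params")) {
    stop_config("params must be an emg_sim_params")
  }
  condition <- match.arg(condition)
  if (params$duration < 10) {
    stop_config("duration must be at least 10 s (baseline windows undefined)")
  }
  fs <- params$sampling_rate
  block_n <- round(fs) # 1-s synthesis blocks, matching the analysis window
  n_blocks <- floor(params$duration * fs / block_n)
  with_seed(seed, {
    decay <- params$mdf_decay_rate[[condition]]
    baseline_i <- max(stats::rnorm(1, params$baseline_mdf[[condition]],
                                   params$baseline_mdf_sd[[condition]]),
                      params$f_low + 10)
    mdf0 <- baseline_i + 5 * decay # first-10-s mean equals the drawn baseline
    target_ratio <- params$cocontraction_ratio_target[[condition]]
    ratio <- if (target_ratio == 0) 0 else
      max(stats::rnorm(1, target_ratio, params$cocontraction_ratio_sd[[condition]]), 0)
    f0 <- max(stats::rnorm(1, params$force_baseline[[condition]],
                           params$force_baseline_sd[[condition]]), 1)
    t_half <- max(stats::rnorm(1, params$force_decay_halftime[[condition]],
                               params$force_decay_halftime_sd[[condition]]), 12)
    subj_onset <- max(stats::rnorm(1, params$subjective_onset_mean[[condition]],
                                   params$subjective_onset_sd[[condition]]), 10)

    ag <- params$agonist_amplitude *
      mdf_band_signal(n_blocks, block_n, fs, params$f_low, mdf0, decay)
    if (ratio > 0) {
      ant <- ratio * params$agonist_amplitude *
        mdf_band_signal(n_blocks, block_n, fs, params$f_low, mdf0, 0)
    } else {
      ant <- numeric(length(ag))
    }

    tt <- (seq_len(n_blocks * block_n) - 1) / fs
    lambda <- force_decay_lambda(t_half)
    force <- f0 * exp(-lambda * tt)
    if (params$force_noise_sd > 0) {
      force <- pmax(force + stats::rnorm(length(force), 0, params$force_noise_sd), 0)
    }

    list(
      agonist = emg_recording(ag, fs, "agonist", condition),
      antagonist = emg_recording(ant, fs, "antagonist", condition),
      force = force_trace(force, fs, condition),
      subjective_onset_s = subj_onset,
      true = list(baseline_mdf = baseline_i, mdf0 = mdf0,
                  cocontraction_ratio = ratio, force0 = f0,
                  force_halftime = t_half, lambda = lambda)
    )
  })
}

# decay rate such that F0*exp(-lambda*t) crosses half of its first-10-s mean
# exactly at t_half: exp(-lambda*t_half) = (1 - exp(-10 lambda)) / (20 lambda)
force_decay_lambda <- function(t_half) {
  f <- function(l) exp(-l * t_half) - (1 - exp(-10 * l)) / (20 * l)
  stats::uniroot(f, c(1e-6, 2), tol = 1e-12)$root
}

#' Analytic MDF fatigue-onset time for the simulated decay
#'
#' With a linear MDF decline starting at `m0 = baseline + 5 r` (so the
#' first-10-s mean equals `baseline`), the >`drop_frac` fall below baseline
#' is crossed at `t = drop_frac * baseline / r + 5`. Used to cross-check
#' the windowed detector against the generator.
#'
#' @param baseline_mdf First-10-s mean MDF (Hz).
#' @param decay_rate Linear decline rate (Hz/s).
#' @param drop_frac Fractional drop (default 0.10).
#' @return Crossing time in seconds.
#' @export
analytic_mdf_onset <- function(baseline_mdf, decay_rate, drop_frac = 0.10) {
  if (decay_rate <= 0) return(Inf)
  drop_frac * baseline_mdf / decay_rate + 5
}
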