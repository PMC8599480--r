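# Synthetic cohort generator.
#
# Emulates the longitudinal study design: patients followed from a single
# pre-operative visit through ~2 years of 3-monthly appointments, with muscle
# volume per unit BMI recovering from a denervated baseline towards a
# subject-specific asymptote, MRC grade and SPONEA derived from volume, and
# replicate measurements for reproducibility studies. All calibration
# defaults come from the published per-grade and healthy-control volume
# distributions.

#' Per-grade volume calibration
#'
#' Mean and SD of muscle volume per unit BMI (mL per kg/m^2) for MRC grades
#' 0-5. Grades 0-4 are reinnervated muscles; grade 5 is the healthy-control
#' distribution.
#'
#' @return Data frame with columns `grade`, `mean`, `sd`.
#' @export
default_grade_calibration <- function() {
  data.frame(
    grade = 0:5,
    mean = c(2.28, 3.20, 3.96, 4.57, 8.37, 10.76),
    sd = c(0.70, 0.56, 0.81, 1.36, 2.49, 1.42)
  )
}

#' Trajectory parameters for volume recovery
#'
#' Delayed saturating-exponential recovery of volume per unit BMI:
#' `v(t) = baseline + (asymptote - baseline) * (1 - exp(-rate * (t - onset)))`
#' for `t >= onset`, constant at baseline before. Subject-level random
#' effects perturb the asymptote, onset and log-rate; pre-operative visits
#' sit at the denervated baseline.
#'
#' @param baseline_volume_per_bmi Denervated baseline mean (mL/BMI).
#' @param baseline_sd Between-subject SD of the baseline.
#' @param asymptote_volume_per_bmi Mean recovery asymptote (mL/BMI); the
#'   default is the grade-4 calibration mean, the typical plateau of
#'   reinnervated muscle.
#' @param asymptote_sd Between-subject SD of the asymptote.
#' @param onset_delay_days Mean delay before volume starts rising (days).
#' @param onset_sd Between-subject SD of the delay.
#' @param rate Mean recovery rate (1/days); `1/300` reaches ~95% of the
#'   plateau by about 2.5 years post-onset, matching the observed 0-1700 day
#'   recovery span.
#' @param log_rate_sd Between-subject SD of the log rate.
#' @param observation_noise_sd Visit-level measurement noise SD (mL/BMI).
#' @return A `trajectory_params` list.
#' @export
trajectory_params <- function(baseline_volume_per_bmi = 2.28,
                              baseline_sd = 0.50,
                              asymptote_volume_per_bmi = 8.37,
                              asymptote_sd = 2.49,
                              onset_delay_days = 60,
                              onset_sd = 25,
                              rate = 1 / 300,
                              log_rate_sd = 0.25,
                              observation_noise_sd = 0.5) {
  check_scalar_number(baseline_volume_per_bmi, "baseline_volume_per_bmi", 0)
  check_scalar_number(asymptote_volume_per_bmi, "asymptote_volume_per_bmi", 0)
  if (asymptote_volume_per_bmi < baseline_volume_per_bmi) {
    stop_config("asymptote must be >= baseline")
  }
  check_scalar_number(onset_delay_days, "onset_delay_days", 0)
  check_scalar_number(rate, "rate", 0, strict_lower = TRUE)
  for (nm in c("baseline_sd", "asymptote_sd", "onset_sd", "log_rate_sd",
               "observation_noise_sd")) {
    check_scalar_number(get(nm), nm, 0)
  }
  structure(
    list(
      baseline_volume_per_bmi = baseline_volume_per_bmi,
      baseline_sd = baseline_sd,
      asymptote_volume_per_bmi = asymptote_volume_per_bmi,
      asymptote_sd = asymptote_sd,
      onset_delay_days = onset_delay_days,
      onset_sd = onset_sd,
      rate = rate,
      log_rate_sd = log_rate_sd,
      observation_noise_sd = observation_noise_sd
    ),
    class = "trajectory_params"
  )
}

#' Cohort generator configuration
#'
#' @param n_subjects Number of patients (>= 1).
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @param followup_range_days Length-2 interval of days post-op covered by
#'   the study (negative = pre-operative).
#' @param visit_schedule Either `"quarterly"` (a visit every 91 days from
#'   day 0 to the end of follow-up, mirroring 3-monthly re-invitations) or a
#'   numeric vector of visit days applied to every subject.
#' @param include_preop Logical; add one pre-operative visit at the start of
#'   `followup_range_days` (default `TRUE` when the range extends below 0).
#' @param bmi_mean,bmi_sd Body-mass-index distribution (kg/m^2); BMI is
#'   re-measured at each visit with small within-subject variation.
#' @param healthy_volume_per_bmi_mean,healthy_volume_per_bmi_sd
#'   Healthy-control volume per unit BMI distribution.
#' @param grade_calibration Per-grade volume distribution table
#'   ([default_grade_calibration()]); grade means must be strictly
#'   increasing with grade.
#' @param sponea_noise_sd SD (percentage points) of the noise added to the
#'   latent SPONEA mapping before decile quantisation.
#' @param trajectory A [trajectory_params()] object.
#' @param emg_params An [emg_sim_params()] object.
#' @return A validated `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 25,
                          seed = 1L,
                          followup_range_days = c(-90, 1700),
                          visit_schedule = "quarterly",
                          include_preop = NULL,
                          bmi_mean = 25,
                          bmi_sd = 2,
                          healthy_volume_per_bmi_mean = 10.76,
                          healthy_volume_per_bmi_sd = 1.42,
                          grade_calibration = default_grade_calibration(),
                          sponea_noise_sd = 5,
                          trajectory = trajectory_params(),
                          emg_params = emg_sim_params()) {
  if (!is.numeric(n_subjects) || length(n_subjects) != 1L || n_subjects < 1) {
    stop_config("n_subjects must be >= 1")
  }
  check_scalar_number(seed, "seed")
  if (length(followup_range_days) != 2L ||
      followup_range_days[2] <= followup_range_days[1]) {
    stop_config("followup_range_days must be an increasing length-2 interval")
  }
  if (is.character(visit_schedule)) {
    if (!identical(visit_schedule, "quarterly")) {
      stop_config("visit_schedule must be 'quarterly' or a numeric vector of days")
    }
  } else {
    if (length(visit_schedule) == 0L || any(!is.finite(visit_schedule))) {
      stop_config("visit_schedule must be non-empty with finite days")
    }
  }
  if (is.null(include_preop)) include_preop <- followup_range_days[1] < 0
  check_scalar_number(bmi_mean, "bmi_mean", 0, strict_lower = TRUE)
  check_scalar_number(bmi_sd, "bmi_sd", 0, strict_lower = TRUE)
  check_scalar_number(healthy_volume_per_bmi_mean,
                      "healthy_volume_per_bmi_mean", 0, strict_lower = TRUE)
  check_scalar_number(healthy_volume_per_bmi_sd,
                      "healthy_volume_per_bmi_sd", 0, strict_lower = TRUE)
  validate_grade_calibration(grade_calibration)
  check_scalar_number(sponea_noise_sd, "sponea_noise_sd", 0)
  stopifnot(inherits(trajectory, "trajectory_params"),
            inherits(emg_params, "emg_sim_params"))
  structure(
    list(
      n_subjects = as.integer(n_subjects), seed = as.integer(seed),
      followup_range_days = followup_range_days,
      visit_schedule = visit_schedule, include_preop = include_preop,
      bmi_mean = bmi_mean, bmi_sd = bmi_sd,
      healthy_volume_per_bmi_mean = healthy_volume_per_bmi_mean,
      healthy_volume_per_bmi_sd = healthy_volume_per_bmi_sd,
      grade_calibration = grade_calibration,
      sponea_noise_sd = sponea_noise_sd,
      trajectory = trajectory, emg_params = emg_params
    ),
    class = "cohort_config"
  )
}

validate_grade_calibration <- function(cal) {
  if (!is.data.frame(cal) || !all(c("grade", "mean", "sd") %in% names(cal))) {
    stop_config("grade_calibration must have columns grade, mean, sd")
  }
  if (any(cal$sd <= 0)) stop_config("grade calibration SDs must be > 0")
  if (any(diff(cal$mean[order(cal$grade)]) <= 0)) {
    stop_config("grade calibration means must be strictly increasing with grade")
  }
  invisible(cal)
}

expected_trajectory <- function(traj, days) {
  rise <- 1 - exp(-traj$rate * pmax(days - traj$onset_delay_days, 0))
  traj$baseline_volume_per_bmi +
    (traj$asymptote_volume_per_bmi - traj$baseline_volume_per_bmi) * rise
}

#' Most likely MRC grade for an observed volume
#'
#' Evaluates the per-grade Gaussian calibration densities at the observed
#' volume per unit BMI and returns the maximum-likelihood grade; ties break
#' towards the lower grade. Monotone non-decreasing in volume over the
#' clinically observed range (the heavier grade-4 tail overtakes grade 5
#' only far above healthy volumes).
#'
#' @param volume_per_bmi Non-negative volume(s) per unit BMI.
#' @param calibration Per-grade calibration table
#'   ([default_grade_calibration()]).
#' @return Integer MRC grade(s) in 0-5.
#' @export
grade_from_volume <- function(volume_per_bmi,
                              calibration = default_grade_calibration()) {
  validate_grade_calibration(calibration)
  if (any(!is.finite(volume_per_bmi)) || any(volume_per_bmi < 0)) {
    stop_input("volume_per_bmi must be finite and non-negative")
  }
  cal <- calibration[order(calibration$grade), ]
  ll <- vapply(seq_len(nrow(cal)), function(g) {
    stats::dnorm(volume_per_bmi, cal$mean[g], cal$sd[g], log = TRUE)
  }, numeric(length(volume_per_bmi)))
  ll <- matrix(ll, nrow = length(volume_per_bmi))
  cal$grade[apply(ll, 1L, which.max)]
}

#' SPONEA score implied by a volume measurement
#'
#' The latent mapping is piecewise linear between the scale endpoints (zero
#' volume scores 0%, the healthy-control mean scores 100%); Gaussian noise
#' is added, then the score is quantised to the 11-point decile scale and
#' clipped to \[0, 100\].
#'
#' @param volume_per_bmi Non-negative volume(s) per unit BMI.
#' @param noise_sd Noise SD in percentage points (>= 0).
#' @param healthy_mean Volume per unit BMI mapped to 100%.
#' @return SPONEA score(s) in `{0, 10, ..., 100}`.
#' @export
sponea_from_volume <- function(volume_per_bmi, noise_sd = 5,
                               healthy_mean = 10.76) {
  if (any(!is.finite(volume_per_bmi)) || any(volume_per_bmi < 0)) {
    stop_input("volume_per_bmi must be finite and non-negative")
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0) {
    stop_config("noise_sd must be a non-negative number")
  }
  latent <- 100 * volume_per_bmi / healthy_mean
  if (noise_sd > 0) {
    latent <- latent + stats::rnorm(length(latent), 0, noise_sd)
  }
  pmin(pmax(10 * round(latent / 10), 0), 100)
}

#' Generate a synthetic longitudinal cohort
#'
#' Draws per-subject recovery trajectories (delayed saturating-exponential
#' rise of volume per unit BMI), samples visits on the configured schedule
#' (plus one pre-operative visit at baseline volume when enabled), adds
#' visit-level measurement noise, and derives MRC grade and SPONEA from the
#' observed volume. Fully reproducible from `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return Data frame with one row per subject-visit: `subject`, `day`,
#'   `bmi`, `volume_ml`, `volume_per_bmi`, `mrc`, `sponea`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    stop_config("config must be a cohort_config")
  }
  traj <- config$trajectory
  with_seed(config$seed, {
    if (is.character(config$visit_schedule)) {
      days <- seq(0, config$followup_range_days[2], by = 91)
    } else {
      days <- sort(unique(as.numeric(config$visit_schedule)))
    }
    if (config$include_preop && all(days >= 0)) {
      days <- c(config$followup_range_days[1], days)
    }
    rows <- lapply(seq_len(config$n_subjects), function(s) {
      baseline <- max(stats::rnorm(1, traj$baseline_volume_per_bmi,
                                   traj$baseline_sd), 0.2)
      asym <- max(stats::rnorm(1, traj$asymptote_volume_per_bmi,
                               traj$asymptote_sd), baseline)
      onset <- max(stats::rnorm(1, traj$onset_delay_days, traj$onset_sd), 0)
      rate <- traj$rate * exp(stats::rnorm(1, 0, traj$log_rate_sd))
      bmi_subj <- stats::rnorm(1, config$bmi_mean, config$bmi_sd)
      rise <- 1 - exp(-rate * pmax(days - onset, 0))
      mu <- baseline + (asym - baseline) * rise
      mu[days < 0] <- baseline
      vpb <- pmax(mu + stats::rnorm(length(days), 0, traj$observation_noise_sd), 0)
      bmi <- pmax(bmi_subj + stats::rnorm(length(days), 0, 0.5), 15)
      data.frame(
        subject = sprintf("S%03d", s), day = days, bmi = bmi,
        volume_ml = vpb * bmi, volume_per_bmi = vpb,
        mrc = grade_from_volume(vpb, config$grade_calibration),
        sponea = sponea_from_volume(vpb, config$sponea_noise_sd,
                                    config$healthy_volume_per_bmi_mean)
      )
    })
    do.call(rbind, rows)
  })
}

#' Generate healthy-control measurements
#'
#' Draws healthy subjects with volume per unit BMI from the uninjured
#' calibration and a per-subject BMI, returning the raw muscle volume so
#' the normalisation path ([normalize_by_bmi()]) can be exercised end to
#' end.
#'
#' @param n Number of controls.
#' @param config A [cohort_config()] supplying the calibration.
#' @param seed Optional seed overriding `config$seed`.
#' @return Data frame with `subject`, `bmi`, `volume_ml` and the generating
#'   `volume_per_bmi`.
#' @export
generate_healthy_controls <- function(n, config = cohort_config(),
                                      seed = config$seed) {
  if (n < 1) stop_config("n must be >= 1")
  with_seed(seed, {
    vpb <- pmax(stats::rnorm(n, config$healthy_volume_per_bmi_mean,
                             config$healthy_volume_per_bmi_sd), 0)
    bmi <- pmax(stats::rnorm(n, config$bmi_mean, config$bmi_sd), 15)
    data.frame(
      subject = sprintf("H%05d", seq_len(n)), bmi = bmi,
      volume_ml = vpb * bmi, volume_per_bmi = vpb
    )
  })
}

#' Generate replicate volume measurements for reproducibility studies
#'
#' Builds a two-way (target x rater) table `y_ij = v_i + r_j + e_ij` with
#' additive rater effects and residual (scan/session) error, emulating
#' scan-rescan and inter-/intra-investigator designs. The population
#' intraclass correlation implied by the variance components,
#' `var(v) / (var(v) + rater_sd^2 + residual_sd^2)`, is returned alongside
#' the table.
#'
#' @param true_volumes Numeric vector of true target volumes (mL).
#' @param rater_sd SD of the additive per-rater bias (>= 0).
#' @param residual_sd SD of the residual measurement error (>= 0).
#' @param n_raters Number of raters/replicates (>= 2).
#' @param seed Optional seed.
#' @return List with `table` (long data frame `target`, `rater`, `value`)
#'   and `implied_icc`.
#' @export
generate_replicate_volumes <- function(true_volumes, rater_sd, residual_sd,
                                       n_raters = 2L, seed = NULL) {
  if (length(true_volumes) < 2L) stop_config("need at least 2 targets")
  if (n_raters < 2L) stop_config("n_raters must be >= 2")
  if (rater_sd < 0 || residual_sd < 0) {
    stop_config("error SDs must be non-negative")
  }
  n <- length(true_volumes)
  with_seed(seed, {
    rater_effects <- stats::rnorm(n_raters, 0, rater_sd)
    tab <- expand.grid(target = seq_len(n), rater = seq_len(n_raters))
    tab$value <- true_volumes[tab$target] + rater_effects[tab$rater] +
      stats::rnorm(nrow(tab), 0, residual_sd)
    sigma_t2 <- stats::var(true_volumes)
    denom <- sigma_t2 + rater_sd^2 + residual_sd^2
    list(table = tab, implied_icc = if (denom > 0) sigma_t2 / denom else 1)
  })
}
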