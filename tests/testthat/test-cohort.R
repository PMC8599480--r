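test_that("configuration invariants are enforced", {
  expect_error(cohort_config(n_subjects = 0), "n_subjects")
  expect_error(cohort_config(visit_schedule = numeric(0)), "schedule")
  expect_error(cohort_config(visit_schedule = c(0, NA)), "schedule")
  bad_cal <- default_grade_calibration()
  bad_cal$mean[3] <- 10 # not increasing
  expect_error(cohort_config(grade_calibration = bad_cal), "increasing")
  bad_cal <- default_grade_calibration()
  bad_cal$sd[1] <- 0
  expect_error(cohort_config(grade_calibration = bad_cal), "SD")
  expect_error(trajectory_params(rate = 0), "rate")
  expect_error(trajectory_params(baseline_volume_per_bmi = 5,
                                 asymptote_volume_per_bmi = 3), "asymptote")
})

test_that("cohorts are reproducible from the seed", {
  cfg <- cohort_config(n_subjects = 6, seed = 123)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  c2 <- generate_cohort(cohort_config(n_subjects = 6, seed = 124))
  expect_false(identical(a, c2))

  expect_true(all(table(a$subject) >= 1))
  expect_true(all(a$volume_per_bmi >= 0))
  expect_true(all(a$mrc %in% 0:5))
  expect_true(all(a$sponea %in% seq(0, 100, 10)))
  # pre-op visit present with baseline-level volume
  pre <- a[a$day < 0, ]
  expect_equal(nrow(pre), 6)
  expect_lt(mean(pre$volume_per_bmi), 3.5)
})

test_that("late-visit volumes converge to the asymptote distribution", {
  cfg <- cohort_config(n_subjects = 3000, seed = 7,
                       followup_range_days = c(0, 2600),
                       visit_schedule = 2500, include_preop = FALSE)
  coh <- generate_cohort(cfg)
  expect_equal(nrow(coh), 3000)

  # independent oracle: redraw the subject-level parameters with the test's
  # own RNG and evaluate the trajectory arithmetic directly
  traj <- cfg$trajectory
  set.seed(99)
  n <- 20000
  base <- pmax(rnorm(n, traj$baseline_volume_per_bmi, traj$baseline_sd), 0.2)
  asym <- pmax(rnorm(n, traj$asymptote_volume_per_bmi, traj$asymptote_sd), base)
  onset <- pmax(rnorm(n, traj$onset_delay_days, traj$onset_sd), 0)
  rate <- traj$rate * exp(rnorm(n, 0, traj$log_rate_sd))
  mu_oracle <- mean(base + (asym - base) * (1 - exp(-rate * pmax(2500 - onset, 0))))

  se <- sd(coh$volume_per_bmi) / sqrt(nrow(coh))
  expect_lt(abs(mean(coh$volume_per_bmi) - mu_oracle), 3 * se + 0.05)
  # and the asymptote is essentially reached: day 2500 is ~8 mean time constants
  expect_lt(abs(mu_oracle - traj$asymptote_volume_per_bmi), 0.2)
})

test_that("mean trajectory is non-decreasing after onset", {
  cfg <- cohort_config(n_subjects = 400, seed = 31,
                       followup_range_days = c(0, 1700),
                       visit_schedule = seq(91, 1700, by = 91),
                       include_preop = FALSE)
  coh <- generate_cohort(cfg)
  means <- tapply(coh$volume_per_bmi, coh$day, mean)
  diffs <- diff(means)
  # allow Monte-Carlo wiggle well below the visit-to-visit noise SE
  expect_true(all(diffs > -3 * 0.5 / sqrt(400)))
})

test_that("grade assignment is the per-grade maximum likelihood, monotone in volume", {
  expect_identical(grade_from_volume(10.76), 5L)
  expect_identical(grade_from_volume(2.28), 0L)
  expect_identical(grade_from_volume(0), 0L)

  cal <- default_grade_calibration()
  brute <- function(v) {
    dens <- dnorm(v, cal$mean, cal$sd)
    cal$grade[which.max(dens)]
  }
  expect_identical(grade_from_volume(6.2), brute(6.2))
  for (v in seq(0, 12.5, by = 0.25)) {
    expect_identical(grade_from_volume(v), brute(v))
  }
  grades <- grade_from_volume(seq(0, 12.5, by = 0.05))
  expect_true(all(diff(grades) >= 0))
})

test_that("SPONEA mapping hits the scale endpoints and is unbiased mid-scale", {
  expect_equal(sponea_from_volume(10.76, noise_sd = 0), 100)
  expect_equal(sponea_from_volume(0, noise_sd = 0), 0)
  expect_equal(sponea_from_volume(20, noise_sd = 0), 100) # clipped
  expect_error(sponea_from_volume(5, noise_sd = -1), "noise_sd")

  set.seed(17)
  v <- 5.38 # latent score 50
  draws <- sponea_from_volume(rep(v, 10000), noise_sd = 5)
  expect_true(all(draws %in% seq(0, 100, 10)))
  noiseless <- sponea_from_volume(v, noise_sd = 0)
  expect_lt(abs(mean(draws) - noiseless), 3 * sd(draws) / sqrt(10000))
})

test_that("healthy controls reproduce the uninjured calibration through normalisation", {
  cfg <- cohort_config()
  h <- generate_healthy_controls(4000, cfg, seed = 55)
  vpb <- normalize_by_bmi(h$volume_ml, h$bmi)
  expect_equal(vpb, h$volume_per_bmi, tolerance = 1e-12)
  se <- sd(vpb) / sqrt(length(vpb))
  expect_lt(abs(mean(vpb) - 10.76), 3 * se)
  expect_lt(abs(sd(vpb) - 1.42), 0.1)
})

test_that("replicate volume tables carry their implied ICC", {
  vols <- seq(150, 350, length.out = 20)
  # zero error variance: all replicates identical, implied ICC 1
  r0 <- generate_replicate_volumes(vols, 0, 0, n_raters = 3, seed = 1)
  wide <- matrix(r0$table$value, ncol = 3)
  expect_true(all(wide[, 1] == wide[, 2] & wide[, 2] == wide[, 3]))
  expect_equal(r0$implied_icc, 1)

  # residual variance dominating drives the implied ICC towards zero
  rbig <- generate_replicate_volumes(vols, 0, 1e4, seed = 2)
  expect_lt(rbig$implied_icc, 0.01)

  expect_error(generate_replicate_volumes(vols, -1, 1), "non-negative")
  expect_error(generate_replicate_volumes(vols, 1, 1, n_raters = 1), "n_raters")

  # stated components are recovered by the ICC estimator at n = 50 targets
  set.seed(66)
  true_vols <- rnorm(50, 250, 40)
  rr <- generate_replicate_volumes(true_vols, 5, 10, n_raters = 2, seed = 3)
  est <- icc(rr$table)
  expect_gt(rr$implied_icc, est$ci_low)
  expect_lt(rr$implied_icc, est$ci_high)
})

test_that("EMG pair generation is deterministic and calibrated", {
  p <- emg_sim_params()
  a <- generate_emg_pair(p, "injured", seed = 5)
  b <- generate_emg_pair(p, "injured", seed = 5)
  expect_identical(a, b)

  expect_equal(a$agonist$sampling_rate, 1000)
  expect_identical(a$agonist$role, "agonist")
  expect_identical(a$antagonist$role, "antagonist")
  expect_identical(a$force$condition, "injured")

  # a zero co-contraction target silences the antagonist exactly
  p0 <- emg_sim_params(cocontraction_ratio_target = c(uninjured = 0, injured = 0))
  pair0 <- generate_emg_pair(p0, "uninjured", seed = 1)
  expect_true(all(pair0$antagonist$samples == 0))

  expect_error(emg_sim_params(duration = 5) |> generate_emg_pair("injured"),
               "duration")
  # aliasing guard: band must stay below Nyquist
  expect_error(emg_sim_params(sampling_rate = 200), "Nyquist|twice")
})

test_that("generated signals reproduce their drawn per-recording parameters", {
  p <- emg_sim_params()
  for (seed in c(2, 9)) {
    pair <- generate_emg_pair(p, "uninjured", seed = seed)
    fs <- pair$agonist$sampling_rate
    m <- mdf_fatigue_onset(pair$agonist)
    expect_equal(m$baseline_value, pair$true$baseline_mdf, tolerance = 1.5)
    expect_lt(abs(m$onset_time_s -
                    analytic_mdf_onset(pair$true$baseline_mdf,
                                       p$mdf_decay_rate[["uninjured"]])), 2)
    ratio <- cocontraction_ratio(
      area_under_curve(rms_envelope(pair$antagonist), fs),
      area_under_curve(rms_envelope(pair$agonist), fs)
    )
    expect_equal(ratio, pair$true$cocontraction_ratio, tolerance = 0.01)
    f <- force_fatigue_onset(pair$force)
    expect_lt(abs(f$onset_time_s - pair$true$force_halftime), 1.5)
  }
})
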