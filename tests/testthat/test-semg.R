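fs <- 1000

test_that("RMS envelope matches a brute-force sliding window", {
  expect_equal(rms_envelope(rep(-3, 50), 0.01, fs), rep(3, 50))

  # long window over a sinusoid converges to A/sqrt(2)
  t <- (0:9999) / fs
  x <- 2.5 * sin(2 * pi * 50 * t)
  env <- rms_envelope(x, 2, fs)
  mid <- env[3000:7000]
  expect_true(all(abs(mid - 2.5 / sqrt(2)) < 0.01))

  set.seed(5)
  for (width_s in c(0.005, 0.012, 0.05)) {
    x <- rnorm(137)
    expect_equal(rms_envelope(x, width_s, fs),
                 oracle_rms(x, round(width_s * fs)))
  }
  expect_error(rms_envelope(numeric(0), 0.5, fs), "empty")
  expect_error(rms_envelope(rnorm(10), 0.0001, fs), "window")
})

test_that("area under the curve is the trapezoidal integral", {
  expect_equal(area_under_curve(rep(1, 10 * fs + 1), fs), 10)
  # triangle ramp 0 -> 1 over 2 s
  ramp <- seq(0, 1, length.out = 2 * fs + 1)
  expect_equal(area_under_curve(ramp, fs), 1, tolerance = 1e-6)
  # random envelope vs dense Riemann mid-point sum
  set.seed(9)
  env <- abs(rnorm(501))
  dense_t <- seq(0, 500 / fs, length.out = 500001)
  riemann <- sum(approx((0:500) / fs, env, xout = dense_t)$y) *
    (dense_t[2] - dense_t[1])
  expect_equal(area_under_curve(env, fs), riemann, tolerance = 1e-3)
  expect_error(area_under_curve(1, fs), "2 points")
})

test_that("co-contraction ratio behaves like the antagonist/agonist quotient", {
  t <- (0:(5 * fs - 1)) / fs
  x <- abs(sin(2 * pi * 3 * t)) + 0.2
  aoc <- area_under_curve(x, fs)
  expect_equal(cocontraction_ratio(aoc, aoc), 1.0)
  expect_equal(cocontraction_ratio(0, aoc), 0.0)
  # antagonist envelope a fixed fraction of the agonist -> that fraction
  expect_equal(cocontraction_ratio(area_under_curve(0.26 * x, fs), aoc), 0.26)
  # simultaneous rescaling of both channels leaves the ratio unchanged
  expect_equal(cocontraction_ratio(area_under_curve(3.7 * 0.26 * x, fs),
                                   area_under_curve(3.7 * x, fs)), 0.26)
  expect_error(cocontraction_ratio(1, 0), "agonist")
})

test_that("median frequency splits the spectrum into equal power halves", {
  t <- (0:999) / fs
  expect_equal(median_frequency(sin(2 * pi * 50 * t), fs), 50)

  two_tone <- sin(2 * pi * 40 * t) + sin(2 * pi * 80 * t)
  f2 <- median_frequency(two_tone, fs)
  expect_gt(f2, 40)
  expect_lt(f2, 80)
  # unequal amplitudes avoid an exact half-power tie between the two lines
  skewed <- sin(2 * pi * 40 * t) + 1.3 * sin(2 * pi * 80 * t)
  expect_equal(median_frequency(skewed, fs), oracle_mdf(skewed, fs),
               tolerance = 1e-9)

  # flat band on [0, B] has MDF B/2 in expectation
  set.seed(21)
  mdfs <- replicate(40, median_frequency(flat_band_signal(1000, fs, 0, 120), fs))
  expect_equal(mean(mdfs), 60, tolerance = 1.5)

  # amplitude scaling leaves the MDF unchanged
  set.seed(22)
  x <- rnorm(512)
  expect_equal(median_frequency(x, fs), median_frequency(40 * x, fs))

  # the returned frequency does split the binned power in half
  spec <- Mod(fft(x))^2
  n_half <- floor(512 / 2) + 1
  power <- spec[1:n_half]
  power[2:(n_half - 1)] <- power[2:(n_half - 1)] + rev(spec[(n_half + 1):512])
  df <- fs / 512
  f_star <- median_frequency(x, fs)
  edges <- (0:(n_half - 1)) * df - df / 2
  below <- sum(power[(edges + df) <= f_star]) +
    power[findInterval(f_star, edges)] *
    (f_star - edges[findInterval(f_star, edges)]) / df
  expect_equal(below, sum(power) / 2, tolerance = 1e-6 * sum(power))

  expect_error(median_frequency(rep(0, 100), fs), "zero power")
  expect_error(median_frequency(3, fs), "2 samples")
})

test_that("MDF fatigue onset inverts a known linear decay", {
  # constant-spectrum signal never crosses the 10% threshold
  set.seed(31)
  const <- flat_band_signal(20 * fs, fs, 20, 120)
  rec <- emg_recording(const, fs)
  res <- mdf_fatigue_onset(rec)
  expect_true(res$censored)
  expect_equal(res$baseline_value, 70, tolerance = 2)

  # linear decay with known slope: onset within one window of the analytic time
  decay <- 0.5
  base <- 70
  x <- musclemri:::mdf_band_signal(40, fs, fs, 20, base + 5 * decay, decay)
  res <- mdf_fatigue_onset(emg_recording(x, fs))
  expect_false(res$censored)
  expect_equal(res$baseline_value, base, tolerance = 1.5)
  analytic <- analytic_mdf_onset(base, decay)
  expect_lt(abs(res$onset_time_s - analytic), 1.5)
  expect_gte(res$onset_time_s, 10)

  # delaying the decay delays the onset by the same amount
  x_delayed <- musclemri:::mdf_band_signal(40, fs, fs, 20, base + 10 * decay, decay)
  res_d <- mdf_fatigue_onset(emg_recording(x_delayed, fs))
  expect_equal(res_d$onset_time_s - res$onset_time_s, 5, tolerance = 1.001)

  expect_error(mdf_fatigue_onset(emg_recording(rnorm(5 * fs), fs)), "10 s")
})

test_that("force fatigue onset detects the 50% crossing", {
  tt <- (0:(40 * fs - 1)) / fs
  # constant force never fatigues
  res <- force_fatigue_onset(force_trace(rep(20, 40 * fs), fs))
  expect_true(res$censored)
  expect_equal(res$baseline_value, 20)

  # step to 0.49 x baseline at exactly t = 20 s
  step <- ifelse(tt < 20, 10, 4.9)
  res <- force_fatigue_onset(force_trace(step, fs))
  expect_equal(res$onset_time_s, 20)

  # exponential decay: crossing matches the analytic solution within a window
  lambda <- musclemri:::force_decay_lambda(25)
  res <- force_fatigue_onset(force_trace(30 * exp(-lambda * tt), fs))
  expect_false(res$censored)
  expect_lt(abs(res$onset_time_s - 25), 1.001)

  # translation covariance: delaying the decay start delays onset equally
  delayed <- 30 * exp(-lambda * pmax(tt - 4, 0))
  res_d <- force_fatigue_onset(force_trace(delayed, fs))
  base_d <- mean(delayed[1:(10 * fs)])
  crossing <- 4 + log(30 / (0.5 * base_d)) / lambda
  expect_lt(abs(res_d$onset_time_s - crossing), 1.001)

  expect_error(force_fatigue_onset(force_trace(rep(1, 3 * fs), fs)), "10 s")
})

test_that("peak volitional force is the global maximum over contractions", {
  set.seed(41)
  traces <- lapply(1:10, function(i) {
    force_trace(pmax(rnorm(200, 10, 2), 0), 100)
  })
  planted <- traces[[7]]$samples
  planted[53] <- 99.5
  traces[[7]] <- force_trace(planted, 100)
  expect_equal(peak_volitional_force(traces), 99.5)
  expect_equal(peak_volitional_force(force_trace(rep(0, 100), 100)), 0)
  expect_error(peak_volitional_force(list()), "at least one")
})

test_that("percentage difference uses the uninjured arm as reference", {
  expect_equal(percent_difference(10, 10), 0)
  expect_equal(percent_difference(0, 10), 100)
  # published group means for time-to-10%-MDF-drop
  expect_equal(percent_difference(22.84, 32.10), 100 * (32.10 - 22.84) / 32.10)
  expect_equal(percent_difference(22.84, 32.10), 28.85, tolerance = 0.005)
  expect_error(percent_difference(5, 0), "positive")
})

test_that("median frequency agrees with the brute-force scan on random spectra", {
  set.seed(51)
  n <- 500
  for (i in 1:25) {
    f_lo <- runif(1, 0, 60)
    x <- flat_band_signal(n, 500, f_lo, f_lo + runif(1, 30, 150)) +
      0.1 * rnorm(n)
    expect_equal(median_frequency(x, 500), oracle_mdf(x, 500),
                 tolerance = 1e-8)
  }
})
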