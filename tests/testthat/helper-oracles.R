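# Independent oracles used across the suite. These deliberately recompute
# quantities with naive, direct methods (matrix DFTs, explicit loops,
# textbook mean-squares algebra) rather than calling back into the package
# internals they check.

# Equal-power median frequency by direct DFT and a cumulative scan over
# bin intervals (each bin a uniform density over [f_k - df/2, f_k + df/2]).
oracle_mdf <- function(x, fs) {
  n <- length(x)
  k <- 0:(n - 1)
  W <- exp(-2i * pi * outer(k, k) / n) # full DFT matrix, brute force
  spec <- Mod(W %*% x)^2
  n_half <- floor(n / 2) + 1
  power <- spec[1:n_half]
  if (n > 2) {
    for (j in (n_half + 1):n) {
      power[n - j + 2] <- power[n - j + 2] + spec[j]
    }
  }
  df <- fs / n
  half <- sum(power) / 2
  acc <- 0
  for (b in seq_len(n_half)) {
    if (acc + power[b] >= half) {
      f_k <- (b - 1) * df
      return(f_k - df / 2 + df * (half - acc) / power[b])
    }
    acc <- acc + power[b]
  }
  stop("oracle scan failed")
}

# Sliding-window RMS by explicit per-sample loops (centre convention,
# shrinking edge windows).
oracle_rms <- function(x, width) {
  n <- length(x)
  half_lo <- floor((width - 1) / 2)
  half_hi <- width - 1 - half_lo
  out <- numeric(n)
  for (i in seq_len(n)) {
    idx <- max(1, i - half_lo):min(n, i + half_hi)
    out[i] <- sqrt(mean(x[idx]^2))
  }
  out
}

# Shrout-Fleiss ICC(2,1) from explicit mean-squares algebra on a complete
# targets x raters matrix.
oracle_icc21 <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_err <- sum((m - outer(row_m, rep(1, k)) -
                   outer(rep(1, n), col_m) + grand)^2)
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# band-limited noise with a configurable flat band, for spectral tests
flat_band_signal <- function(n, fs, f_lo, f_hi) {
  musclemri:::band_noise_block(n, fs, f_lo, f_hi)
}

small_cohort <- function(n_subjects = 12, seed = 42, max_day = 700) {
  generate_cohort(cohort_config(
    n_subjects = n_subjects, seed = seed,
    followup_range_days = c(0, max_day),
    visit_schedule = seq(0, max_day, by = 91),
    include_preop = FALSE
  ))
}
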