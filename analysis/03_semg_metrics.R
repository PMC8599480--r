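#!/usr/bin/env Rscript
# Stage 3: surface-EMG and force metrics.
#
# Simulates sustained-isometric-contraction recording pairs for injured and
# uninjured arms, runs the full metric battery (baseline MDF, MDF/force
# fatigue onsets, co-contraction ratio, peak force), and compares the two
# arms: group means, t-tests, and the injured-vs-uninjured percentage
# differences in fatigue-onset times.

library(musclemri)

seed <- 42L
n_per_condition <- 40L
out_dir <- "results/analysis"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

params <- emg_sim_params()
battery <- function(condition, seed_base) {
  do.call(rbind, lapply(seq_len(n_per_condition), function(i) {
    pair <- generate_emg_pair(params, condition, seed = seed_base + i)
    fs <- pair$agonist$sampling_rate
    mdf <- mdf_fatigue_onset(pair$agonist)
    frc <- force_fatigue_onset(pair$force)
    data.frame(
      condition = condition, recording = i,
      baseline_mdf_hz = mdf$baseline_value,
      mdf_onset_s = ifelse(mdf$censored, NA, mdf$onset_time_s),
      force_onset_s = ifelse(frc$censored, NA, frc$onset_time_s),
      subjective_onset_s = pair$subjective_onset_s,
      cocontraction_ratio = cocontraction_ratio(
        area_under_curve(rms_envelope(pair$antagonist), fs),
        area_under_curve(rms_envelope(pair$agonist), fs)
      ),
      peak_force_kgf = peak_volitional_force(pair$force)
    )
  }))
}

metrics <- rbind(battery("uninjured", seed * 1000L),
                 battery("injured", seed * 1000L + 500L))
write.csv(metrics, file.path(out_dir, "semg_metrics.csv"), row.names = FALSE)

num_cols <- setdiff(names(metrics), c("condition", "recording"))
means <- aggregate(metrics[num_cols], by = metrics["condition"], mean,
                   na.rm = TRUE)
write.csv(means, file.path(out_dir, "semg_group_means.csv"),
          row.names = FALSE)
print(means, digits = 4)

inj <- means[means$condition == "injured", ]
uni <- means[means$condition == "uninjured", ]
for (metric in c("mdf_onset_s", "force_onset_s", "subjective_onset_s")) {
  message(sprintf("%s: injured %.1f s vs uninjured %.1f s -> %.1f%% difference",
                  metric, inj[[metric]], uni[[metric]],
                  percent_difference(inj[[metric]], uni[[metric]])))
}
for (metric in c("baseline_mdf_hz", "cocontraction_ratio", "peak_force_kgf")) {
  gt <- group_tests(metrics[[metric]], metrics$condition)
  message(sprintf("%s: t-test p = %.3g (%ssignificant)", metric, gt$p_value,
                  if (gt$significant) "" else "not "))
}
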