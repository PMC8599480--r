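#!/usr/bin/env Rscript
# Stage 1: simulate the study cohort.
#
# 25 patients followed from one pre-operative visit (day -86) through
# quarterly appointments up to ~1700 days post-op, plus healthy controls,
# matching the scale of the observed study population. Later stages read
# the tables written here.

library(musclemri)

seed <- 42L
out_dir <- "results/analysis"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- cohort_config(n_subjects = 25, seed = seed)
cohort <- generate_cohort(cfg)
write.csv(cohort, file.path(out_dir, "cohort.csv"), row.names = FALSE)

healthy <- generate_healthy_controls(6, cfg, seed = seed + 1L)
write.csv(healthy, file.path(out_dir, "healthy_controls.csv"),
          row.names = FALSE)

message(sprintf("cohort: %d subjects, %d visits (%d pre-operative)",
                length(unique(cohort$subject)), nrow(cohort),
                sum(cohort$day < 0)))
message(sprintf("volume/BMI range %.2f-%.2f mL; MRC grades %s",
                min(cohort$volume_per_bmi), max(cohort$volume_per_bmi),
                paste(names(table(cohort$mrc)), table(cohort$mrc),
                      sep = ":", collapse = " ")))
message(sprintf("healthy controls (n = %d): mean volume/BMI %.2f mL",
                nrow(healthy), mean(healthy$volume_per_bmi)))
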