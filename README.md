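# musclemri

Analysis toolkit for studying **volumetric MRI as an outcome measure of
muscle reinnervation** after nerve transfer surgery to restore elbow
flexion. It is aimed at clinical researchers who need to quantify how well
an imaging biomarker — elbow flexor muscle volume per unit BMI — tracks the
recovery of reinnervated muscle, and how it relates to clinical power
grades, patient-reported function, muscular fatigue and co-contraction.

Patient-level data from such studies are not publicly available, so the
package also ships a calibrated synthetic cohort generator: every stage of
the analysis is runnable, testable and reproducible without any download.

## What it computes

- **Volumetrics** — muscle volume (mL) from labelled voxel masks with
  acquisition spacing metadata (NIfTI supported), `volume = voxels ×
  in-plane area × (slice thickness + interslice gap) / 1000`,
  normalisation by per-visit BMI, and the muscle/humeral-shaft
  signal-intensity ratio used in reproducibility studies.
- **Surface EMG and force** — RMS envelope, area under the envelope, the
  co-contraction ratio `AOC_antagonist / AOC_agonist`, the equal-power
  median frequency (MDF: the frequency f\* with ∫₀^f\* P(f) df = ½ ∫ P(f)
  df), windowed fatigue-onset detectors (>10% MDF drop, >50% force drop
  from the first-10-s baseline), peak volitional force, and
  injured-vs-uninjured percentage differences `100 (u − i)/u`.
- **Hierarchical Gaussian process (HGP)** — a two-level GP for volume/BMI
  over days post-op, `K = k_pop(t,t′) + 1[same subject]·k_subj(t,t′) +
  σ²_n·1[i=j]` with squared-exponential kernels, fitted by marginal
  likelihood with analytic gradients; 2-D outcome maps `(day, volume/BMI) →
  MRC grade or SPONEA`; leave-one-subject-out MAE and predictive
  log-likelihood; and a two-arm trial power calculator
  `n = ⌈2 (z_{1−α/2} + z_β)² σ²/δ²⌉` with a simulation cross-check.
- **Clinical statistics** — two-way random-effects ICC(2,1) with F-based
  95% CI, Pearson/Spearman responsiveness with the qualitative R²
  classification scale, Student's t-tests and one-way ANOVA with
  Bonferroni-adjusted pairwise comparisons.
- **Synthetic cohort** — recovery trajectories (delayed
  saturating-exponential rise), per-grade Gaussian volume calibration,
  SPONEA decile mapping, band-limited EMG with controlled spectral
  compression, decaying force traces, and replicate-measurement tables
  with a known implied ICC.

## Worked example

```r
library(musclemri)

cfg <- cohort_config(n_subjects = 12, seed = 2024,
                     followup_range_days = c(0, 700),
                     visit_schedule = seq(0, 700, by = 91),
                     include_preop = FALSE)
cohort <- generate_cohort(cfg)
head(cohort, 3)
#>   subject day      bmi volume_ml volume_per_bmi mrc sponea
#> 1    S001   0 27.46271  93.84452       3.417162   1     30
#> 2    S001  91 25.67905  95.57512       3.721910   2     40
#> 3    S001 182 27.24214 133.79646       4.911378   3     40

model <- fit_volume_hgp(cohort)
model
#> Hierarchical Gaussian process model
#>   96 observations, 12 subject(s), 1 input dim(s)
#>   population: variance 5.49, length-scale(s) 291
#>   subject:    variance 2.32, length-scale(s) 403
#>   noise variance 0.285, mean 5.63
#>   log marginal likelihood -127.022

predict_volume(model, c(90, 180, 365))
#>   day     mean variance
#> 1  90 3.302707 2.806872
#> 2 180 4.356099 2.805597
#> 3 365 6.229180 2.804260

evaluate_hgp(cohort, "mrc")
#> HGP evaluation (mrc, loso): MAE 0.104, mean log-likelihood -0.279 over 96 held-out points

power_calculation(delta = 0.20 * 8.37, sd = 2.49)$n_per_group
#> [1] 35
```

Reading the output: each simulated visit carries the measured volume/BMI
and the clinical scores derived from it. The fitted model decomposes the
variation into a shared population recovery process (variance 5.49
(mL/BMI)², length-scale 291 days), per-subject deviations, and measurement
noise. Predictions for an unseen subject rise from ~3.3 mL/BMI at 90 days
towards the recovery plateau, with the predictive variance dominated by
between-subject spread. Leave-one-subject-out cross-validation predicts the
MRC grade of held-out patients with a mean absolute error of ~0.1 grades on
this synthetic cohort, i.e. well within ±1 grade. A trial hoping to detect
a 20% improvement on a mean volume of 8.37 mL/BMI (SD 2.49) with 80% power
at α = 0.05 needs 35 patients per arm.

## The analysis workflow

Numbered drivers under `analysis/` run the study end to end and write
their tables under `results/analysis/`:

```sh
Rscript analysis/01_simulate_cohort.R     # 25-subject cohort + healthy controls
Rscript analysis/02_volumetrics.R         # mask -> volume -> volume/BMI -> intensity ratio
Rscript analysis/03_semg_metrics.R        # fatigue, co-contraction, PVF by arm
Rscript analysis/04_hgp_models.R          # HGP fits, LOSO evaluation, power
Rscript analysis/05_reproducibility_stats.R  # ICC, responsiveness, group tests
```

`run_full_study()` performs the same sequence programmatically from a
single seeded `run_config()` and reproduces byte-identical outputs for
identical configs.

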