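---
title: "Modelling muscle reinnervation with volumetric MRI: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling muscle reinnervation with volumetric MRI: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(musclemri)
```

## The problem

After a nerve transfer to restore elbow flexion, the denervated flexor
muscles are reinnervated over months to years. Tracking that recovery needs
an outcome measure that is reproducible, responsive to the underlying
biology, and related to what the patient can actually do. `musclemri`
implements an analysis built around one candidate biomarker — elbow flexor
muscle volume measured from MRI segmentations and normalised by body mass
index (BMI, kg/m²) — together with the clinical and electrophysiological
measures it is compared against: the MRC (Medical Research Council) 0–5
muscle power grade, the SPONEA patient-reported percentage-of-normal-elbow
score (0–100% in 10% steps), surface-EMG fatigue indices, co-contraction
ratios, and peak volitional force (PVF).

Real patient-level data from such studies are not publicly deposited, so
the package ships a synthetic cohort generator calibrated to the published
group-level distributions. Every analysis stage runs end to end on that
generator, which is first-class, tested code: the statistical structure it
produces is exactly what the downstream models assume, no more.

## The synthetic cohort

**Recovery trajectories.** Volume per unit BMI follows a delayed
saturating-exponential rise,
$v(t) = b + (a - b)\,\bigl(1 - e^{-r\,(t - t_0)_+}\bigr)$,
from a denervated baseline $b$ to a subject-specific asymptote $a$ with
onset delay $t_0$ and rate $r$. Published studies show only the empirical
scatter and a fitted Gaussian-process curve, so the parametric family is a
design choice; this one was picked for monotone biological plausibility and
analytic invertibility (every moment of the generator can be computed in
closed form for testing). Defaults: baseline $2.28 \pm 0.5$ mL/BMI (the
grade-0 calibration mean — muscles start denervated), asymptote
$8.37 \pm 2.49$ (the grade-4 mean: most reinnervated muscles plateau at
grade 4, not at healthy volume), onset $60 \pm 25$ days, rate $1/300$
day$^{-1}$ with 0.25 log-SD (≈95% of plateau by 2.5 years post-onset,
matching a 0–1700-day follow-up window), visit-level measurement noise
0.5 mL/BMI. One pre-operative visit (negative days post-op) sits at the
baseline level. Visits follow either a fixed 3-monthly schedule, mirroring
quarterly re-invitations, or an arbitrary user-supplied day list — the
realised schedule in such studies is irregular, so both are exposed rather
than guessing a distribution.

**Clinical scores.** The per-grade calibration table gives volume/BMI as
Gaussian $\mathcal{N}(\mu_g, \sigma_g^2)$ per MRC grade, with means 2.28,
3.20, 3.96, 4.57, 8.37 for grades 0–4 and 10.76 (±1.42) for healthy
grade 5. `grade_from_volume()` inverts this by maximum likelihood over the
six densities (ties to the lower grade). Because the grade-4 SD is larger
than the grade-5 SD, the grade-4 tail would in principle overtake grade 5
again far above healthy volumes (≈15 mL/BMI); the mapping is monotone
throughout the clinically observed range, and the property tests check
monotonicity there. SPONEA has no published functional form, only a
correlation with volume, so the generator uses the simplest monotone map
consistent with the scale endpoints: piecewise-linear from (0 mL/BMI → 0%)
to (healthy mean → 100%), additive Gaussian noise (default 5 points), then
quantisation to the 11-point decile scale and clipping.

**Surface EMG.** The agonist channel is flat-band Gaussian noise
synthesised per 1-s block in the frequency domain, because a flat band
$[f_{lo}, 2m - f_{lo}]$ has equal-power median frequency exactly $m$: the
block's target MDF is controlled directly, and edge bins get fractional
power so the band edge is not quantised to the bin grid. The per-window MDF
declines linearly at rate $r$ from $m_0 = \text{baseline} + 5r$, which
makes the *first-10-s mean* equal the configured baseline — the published
baselines (73.13 Hz uninjured, 62.90 Hz injured) are themselves first-10-s
means, so that is the quantity the generator calibrates. The default decay
rates (0.270 and 0.353 Hz/s) place the >10% drop at the published mean
onset times (32.10 s and 22.84 s) via the closed form
$t = 0.1\,\text{baseline}/r + 5$. The antagonist is independent band noise
whose RMS is a drawn fraction of the agonist RMS, so the co-contraction
ratio has that fraction as its expectation (a target of exactly zero
silences the channel). The force trace decays exponentially with the rate
solved (by `uniroot`) so the 50%-of-first-10-s-mean crossing lands at the
drawn half-time; the default 60-s contraction keeps right-censoring of the
slowest uninjured onsets rare.

**What the generator does not emulate.** Real sEMG has non-stationary
amplitude, motion artefacts, power-line interference and electrode effects;
real recovery curves can be non-monotone (re-injury, disuse); MRC grading
has rater subjectivity uncoupled from volume; BMI and volume are measured
with correlated errors. Passing tests on this generator therefore
demonstrate that the estimators and models are *correct on data satisfying
their own assumptions* — a necessary condition, not evidence about clinical
data.

## Volumetry

Volume is voxel count × in-plane area × effective slice spacing / 1000
(mL). The acquisition protocol has 3-mm slices with a 0.3-mm interslice
gap; whether published volumes integrated over the gap is not stated, so
the default treats each slice as representative of its gap interval
(effective spacing = thickness + gap) and `include_gap = FALSE` selects
thickness-only integration. Masks are handled in voxel-index space in
acquisition orientation — no world-affine reslicing. BMI is a per-visit
quantity (it is re-measured at each scan appointment), so normalisation
happens per visit, not per subject. The muscle/humeral-shaft intensity
ratio is a plain quotient of region means and is invariant to global
intensity rescaling, which is what makes it usable across scan sessions.

## Surface-EMG operators

The median frequency of a segment is the frequency that splits the
periodogram into halves of equal integrated power. Each discrete bin is
treated as a uniform density over its own frequency interval
$[f_k - \Delta f/2,\, f_k + \Delta f/2]$ and the half-power point is
interpolated linearly inside the bin where it falls: with this convention a
pure tone returns its own frequency exactly and a flat band returns its
midpoint in expectation.

```{r mdf-demo}
t <- (0:999) / 1000
median_frequency(sin(2 * pi * 50 * t), sampling_rate = 1000)
```

Fatigue-onset detection uses consecutive non-overlapping 1-s analysis
windows for both signals: the baseline is the first-10-s mean (of
per-window MDFs, or of raw force), and onset is the start time of the first
window at or after 10 s whose statistic falls below the threshold (90% of
baseline for MDF, 50% for force). The windowed formulation was chosen over
a sliding smoother because it keeps the detector's answer exact on
constructed signals (a step to 0.49× baseline at $t = 20$ s yields onset
20 s, not 20 s plus half a smoothing window) and localises any decay
crossing to within one window. A persistence option (k consecutive
sub-threshold windows) is available because transient spectral dips are
plausible in real recordings; the default is the first crossing. Onsets are
censored, not invented, when the threshold is never crossed.

The co-contraction ratio is the area under the antagonist RMS envelope
divided by the agonist area over the same contraction; the RMS envelope
uses a centred 0.5-s default window with shrinking edges, and areas are
trapezoidal integrals. The injured-vs-uninjured percentage difference is
fixed as $100\,(u - i)/u$ — positive means the injured arm fares worse —
because the published analyses report only magnitudes and a sign convention
had to be chosen once.

## The hierarchical Gaussian process

The recovery model is a two-level GP with additive covariance

$$K(x_i, x_j) = k_{pop}(x_i, x_j)
  + \mathbb{1}[s_i = s_j]\, k_{subj}(x_i, x_j)
  + \mathbb{1}[i = j]\,\sigma_n^2,$$

squared-exponential kernels (per-dimension length-scales) at both levels,
and a fitted constant mean. The shared population process captures the
cohort-average recovery; the per-subject process captures individual
deviation; exchangeability across subjects is what lets held-out subjects
be predicted from the population level. The exact published formulation is
not available, so the additive-kernel construction is this package's
documented choice; the constant mean reflects trajectories starting near a
common denervated baseline, and no discontinuity is modelled at day 0.

Hyperparameters maximise the log marginal likelihood with analytic
gradients (L-BFGS-B on log-scale parameters, bounded by data ranges), with
multiple deterministic restarts that rescale the initial length-scales —
GP likelihoods are multimodal in the length-scale, and the restart grid is
fixed so fits are reproducible without a seed. With a single subject the
subject-level variance is unidentifiable and is pinned to zero, reducing to
an ordinary GP. A small escalating jitter guards the Cholesky factor.

MRC and SPONEA are mapped from the 2-D input (day, volume/BMI) as
continuous regression targets: MRC predictions are additionally rounded and
clipped to 0–5, and SPONEA is modelled on the decile scale (score/10) so
that "one point" means one decile — a 1.7-point error against a
"within two points" claim only makes sense on that scale, and the
conversion is applied once at the model boundary. An ordinal likelihood
would be the principled extension but is not the default, since the
published errors are themselves reported on the numeric grade scale.

Evaluation defaults to leave-one-subject-out (the published validation
scheme is unstated; LOSO is the honest choice for a model whose clinical
use is predicting a *new* patient): each fold refits the hyperparameters,
held-out subjects are predicted as new subjects, MAE is reported on the
outcome's native scale and the mean predictive log density under the
Gaussian posterior (noise included) accompanies it.

**Parameter recovery.** The fitting code is validated by simulating
cohorts of 30 subjects × 6 visits from known hyperparameters and refitting
across 20 seeds. The single shared population realisation identifies the
population variance only up to its effective degrees of freedom
(≈ span/length-scale), so the simulation uses a 40-day population
length-scale over a 0–700-day span with per-subject jittered visit times —
enough degrees of freedom that the median relative error of the recovered
population variance and length-scale stays within 30%, which is what the
acceptance suite asserts. Shorter spans or longer length-scales make the
variance genuinely unidentifiable from one realisation; that is a property
of the model class, not of the optimiser.

## Reproducibility and responsiveness statistics

The ICC is fixed to the single-measure absolute-agreement two-way
random-effects form, ICC(2,1): scan-rescan and rater designs treat both
targets and raters as random, and absolute agreement (not consistency) is
what matters when a rater's constant bias would corrupt longitudinal
volume comparisons. The consistency variant ICC(3,1) is available by flag.
Confidence intervals use the F-distribution approximation with
Satterthwaite degrees of freedom; the implementation is verified against
hand-evaluated mean-squares algebra and an independent reference
implementation on a classic worked table.

Correlation-based responsiveness reports $r$, $R^2$, the p-value and a
qualitative label on the R² scale (≤0.3 poor up to >0.8 very good). The
scale's printed boundaries touch, so intervals are implemented
left-open/right-closed: $R^2 = 0.3$ classifies as poor, 0.73 as good. The
Pearson/Spearman choice is automatic (Shapiro-Wilk screen on both
variables at the 5% level) with explicit override. Group comparisons use a
two-tailed Student's t-test for two groups and one-way ANOVA with
Bonferroni-adjusted all-pairs comparisons (pooled SD) beyond that, at the
0.05 level throughout.

## Power calculation

The two-arm sample size uses the two-sided normal approximation
$n = \lceil 2 (z_{1-\alpha/2} + z_{\beta})^2 \sigma^2 / \delta^2 \rceil$
per group, with the effect expressible directly, as a fraction of a mean
volume, or from a fitted volume model at a planned assessment day (mean
from the population posterior, SD from the subject-level plus noise
variances). A simulation mode re-estimates power at the analytic $n$ by
repeated two-sample t-tests. Because the ceiling only partially offsets
the normal approximation's optimism, the exact t-test power at the
returned $n$ sits marginally below nominal — the cross-check in the test
suite therefore compares the simulation against the exact t-test power,
not against the nominal target.

```{r power-demo}
power_calculation(delta = 0.20 * 8.37, sd = 2.49)$n_per_group
```

## Problem sizes and runtime choices

The validation suite uses 20–25-subject cohorts with quarterly visits over
0–700 days (≈200 visits) for the cross-validated evaluations, 60–500
simulated EMG pairs for the calibration checks, 10,000 draws for
large-sample means, and 20 seeds for the hyperparameter-recovery study.
These sizes were chosen so every Monte-Carlo assertion has its tolerance
set by explicit standard-error arithmetic (3 SE unless stated) while the
whole suite stays comfortably interactive.

## Known limitations

- The generator's grade assignment derives MRC from the *observed* noisy
  volume, so volume and grade are more tightly coupled than in clinic,
  where grading is an independent physical exam; cross-validated grade
  errors on synthetic cohorts are accordingly optimistic lower bounds.
- The additive two-level squared-exponential kernel cannot express
  monotonicity; predictions can dip between sparse late visits.
- The windowed fatigue detectors localise onset only to window resolution
  (1 s by default).
- The SPONEA map is linear in volume by construction; any true
  nonlinearity between muscle bulk and perceived function is outside the
  generator.
- Reported volumes depend on the gap convention (3.3 vs 3.0 mm effective
  spacing ≈ 10% of volume); comparisons across configurations must fix it.

## Repository layout

The package follows an analysis-workflow layout: the numbered scripts
under `analysis/` are thin narrative drivers (simulate → volumetrics →
sEMG → HGP → statistics) that write their tables under `results/`, while
every computation lives in the package functions so the test suite and
`scripts/acceptance.R` exercise the same code paths.
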