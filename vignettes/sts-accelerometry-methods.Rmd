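---
title: "Methods: smartphone sit-to-stand accelerometry, reliability, and internally validated risk models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: smartphone sit-to-stand accelerometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its methods: the measurement
model, the classification criteria, the prediction-model validation scheme,
what the synthetic-data generator does and does not emulate, and the
numerical and design choices that were genuinely open.

## Measurement model

A smartphone fixed to the lower abdomen records triaxial acceleration of a
single sit-to-stand transition at a nominal 60 Hz. Because the device frame
rotates with the body, the pipeline works on the Euclidean norm of the three
axes, which is invariant to any rigid rotation of the sensor. The norm is
low-pass filtered by a discrete-Fourier-transform brick wall: every
frequency bin strictly above the cutoff (default 7.5 Hz, below the band of
voluntary trunk movement but above postural sway and the transition itself)
is zeroed conjugate-symmetrically and the signal inverse-transformed. The
brick wall is the literal reading of an "inverse-FFT low-pass"; it is
idempotent, exactly preserves in-band content, and its known cost — Gibbs
ringing near sharp features — is mitigated in practice by the ≥ 1 s quiet
margins the measurement protocol guarantees at both ends of a recording. An
optional raised-cosine taper (`taper` argument, Hz) is exposed for short or
margin-less traces.

Two *gravity dialects* are supported because consumer APIs report either
specific force (gravity included) or linear acceleration (gravity removed):

* **gravity-included** (default): with near-vertical movement the filtered
  norm is ≈ g + d(t); subtracting standard gravity g = 9.80665 m/s²
  recovers the signed dynamic acceleration d(t), negative during the
  unweighting dip.
* **gravity-excluded**: the norm is already the dynamic magnitude |d(t)|.

The signed signal is the one on which the event definitions are coherent:
the magnitude signal folds the unweighting dip onto zero, which makes the
"lowest acceleration" onset ill-posed (any quiet-sit sample ties) and
aliases oscillation harmonics above the cutoff. The gravity-included
dialect is therefore the default and the one for which sample-exact event
recovery is guaranteed; the excluded dialect is supported end-to-end but
documented as recovering the peak within filter tolerance only.

## Event definitions

On the filtered dynamic signal:

* **onset** — the sample of lowest acceleration between the recording start
  and the global maximum. Restricting the search to before the global
  maximum prevents post-peak oscillation troughs from being selected;
  recording start stands in for "start of the motion" because recording
  begins at the audio cue. Ties break to the earliest sample.
* **peak** — the highest acceleration strictly after onset (earliest tie).
* **stabilization** — the first sample after the peak whose trailing-window
  peak-to-peak range is ≤ 1% of g. "Variation" is not further specified by
  the criterion, so the package operationalizes it as the range over a
  trailing window of 0.2 s (12 samples at 60 Hz) — the simplest statistic
  consistent with "variation ≤ 0.01 g"; both the window and threshold are
  arguments. If no sample qualifies, the trial is flagged *never
  stabilized*. There is no time cap on the search within the trace (the
  protocol's 3 s hold bounds it physically); the window is config-exposed
  precisely because these choices are not canonical.

T1 = (peak − onset)/rate, T2 = (stabilization − peak)/rate, and peak force
is peak dynamic acceleration × body mass. Trials whose detectors fail (no
rise after start, never stabilized) are flagged invalid and excluded with a
logged reason; when exactly one of the two trials of a pair is valid, its
values are carried forward with a degradation flag, otherwise the
participant-level value is the mean of the two trials (the temporal
measures are too unreliable for a single trial to stand alone, see below).

## Reliability

Trial-pair reproducibility and device agreement both use ICC(2,1): the
single-measurement, absolute-agreement intraclass correlation from the
two-way subjects × raters decomposition,

$$\mathrm{ICC}(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E)}.$$

The estimator is implemented from its mean squares (returned for audit) and
negative estimates are reported as computed rather than truncated, which
property tests rely on. The common "two-way mixed-effects" phrasing shares
this same point estimate, so no separate variant is needed. No F-based
confidence intervals are produced. For device agreement the two recordings
are resampled to a common rate, aligned by normalized cross-correlation
(lag window ± 2 s, bounded by the protocol's start cue; ≥ 50% overlap;
ties toward zero lag), restricted to the movement phase (onset through
stabilization), and the time samples are treated as "subjects" with the
devices as two raters.

## Classification criteria

Sarcopenia (AWGS2019): SMI < 7.0 (men) / 5.7 (women) kg/m² **and** (grip
< 28 / 18 kgf **or** gait speed < 1.0 m/s). Frailty (J-CHS): at least 3 of
weight loss, weakness (grip cutoffs as above), exhaustion, slowness
(< 1.0 m/s), low activity, with the three self-report components taken as
given flags. All comparisons are strict, per the criteria's wording
("below", "less than", "slower than"); equality at a cutoff is a non-case.
Severity is not graded. Summary percentages are rounded half away from
zero to one decimal, matching cohort-table conventions (base R rounds half
to even).

## Prediction models and internal validation

Five models per outcome: age + sex; walking speed; grip strength; the
smartphone model (age, sex, peak force, T1, T2); and the reduced smartphone
model (age, sex, peak force). Each is an elastic-net penalized logistic
regression with mixing 0.5, continuous predictors z-scored (binary
indicators left as 0/1), and an unpenalized intercept. The penalty strength
is fixed but deliberate: the default corresponds to unit inverse
regularization on the summed log-likelihood scale (strength/n on the
mean-likelihood scale the solver uses), the convention of the common
machine-learning default; it is an argument, not a tuned constant. The fit
is delegated to coordinate descent (`glmnet`) at a tight tolerance along a
short warm-start path, making it deterministic; at vanishing strength it
reproduces the unpenalized maximum-likelihood fit, which the tests verify
against `glm()`.

Internal validation is Harrell's bootstrap optimism correction: for each of
B resamples (default 500) the *entire* pipeline — including re-estimation
of the standardization — is refitted on the resample; the difference
between the resample AUC and the refit's AUC on the original data estimates
the optimism, and the corrected AUC is the apparent AUC minus its mean.
Refitting the standardization inside the loop avoids information leakage
even though it is rarely spelled out. Three reporting choices were open and
are resolved as follows, with both alternatives emitted where cheap:

* the "bootstrap AUC (mean)" averages the resample-apparent AUCs (not the
  test-on-original AUCs, which drive the optimism instead);
* the corrected-AUC CI is the percentile interval of the per-resample
  corrected values (apparent − optimism_b);
* calibration slope and intercept (logistic recalibration: slope from a
  refit of outcome on the linear predictor, intercept from a fixed-slope
  offset fit) are reported apparent *and* optimism-corrected.

Resamples in which either outcome class has fewer than two members cannot
be refitted and are redrawn, keeping B fixed; the redraw count is logged.
Sensitivity and specificity are taken at the Youden-optimal threshold
(maximizing sensitivity + specificity − 1 over observed cutpoints, lowest
threshold on ties) of the apparent predictions — the threshold rule is not
canonical either, so it is config-exposed.

## The synthetic cohort generator

No cohort data are deposited, so the generator emulates the published study
conditions and supplies ground truth for every estimator: 569 participants,
a 223/364 male/female split, classifier-emergent prevalences of 16.7%
(sarcopenia) and 9% (frailty), status-conditional means and SDs of grip
strength, gait speed, SMI, peak force and age taken from the published
tables, self-report frailty-component probabilities from the published
component counts, and a trial-pair peak-force reliability of ICC 0.863.

Design choices worth recording:

* **Status-first with calibration.** Latent sarcopenia and frailty
  liabilities (correlation 0.3) are thresholded to generative statuses;
  measures are drawn from status-conditional normals. Because
  classification operates on the drawn measures, the emergent prevalence
  differs from the drawn rate; draw rates are calibrated by a documented
  one-dimensional search (the emergent rate is linear in the draw rate, so
  the search estimates the two conditional classification rates from a
  Monte-Carlo sample and solves, iterating three times; profiles with under
  five points of separation fall back to the target itself).
* **Classifier consistency.** The published conditional moments are
  conditional on *classified* status. Under pure mixing, about half the
  emergent cases would be drawn controls, regressing every non-classifier
  variable (age, peak force) toward the null and breaking the observed
  model ordering. By default the generator therefore redraws a subject's
  measures until the criteria reproduce the drawn statuses (rejection
  sampling; `enforce_consistency`). This keeps conditional moments faithful
  at the cost of mild truncation of the classifier variables' conditional
  distributions. With the flag off, the pure status-mixture model of the
  calibration search is recovered exactly.
* **Sex decomposition.** Only pooled grip/SMI moments are published, but
  the cutoffs are sex-specific, and the pooled SMI normal would put most
  control men under the male cutoff. Grip and SMI are therefore decomposed
  into sex-by-status cells whose 38/62 mixture approximately restores the
  pooled moments; peak force, gait speed and age remain sex-neutral so
  their configured conditional moments are exact.
* **Correlation structure.** A single latent "function" factor with
  loadings 0.4–0.5 induces positive co-movement among grip, speed, SMI and
  peak force; the published tables imply co-movement but report no
  correlations.
* **Traces.** Each trial is a phenomenological template: quiet sit, a
  half-cosine unweighting dip (depth 30% of the peak), a cosine rise over
  the nominal T1, then a decaying oscillation (2.5 Hz, (1+x)e^(−x)
  envelope joining the peak with zero slope) whose decay constant is set so
  the range criterion is crossed near the nominal T2, followed by ≥ 3 s of
  quiet stance. The template is band-limited below the analysis cutoff at
  generation (7 Hz brick wall) because its piecewise corners are
  construction artifacts, not physics; the clean band-limited signal *is*
  the simulated motion, and ground-truth events are the definitional rules
  applied to it (nominal T1/T2 are realized within ~2 samples). The trace
  is emitted through an arbitrary rigid rotation, with gravity included or
  excluded per dialect, plus per-axis Gaussian noise (default SD
  0.05 m/s²) and an optional 17 Hz component that exercises the filter.
  On noiseless gravity-included traces the full pipeline recovers all three
  events exactly, which the acceptance tests assert at ±1 sample.
* **Reliability targeting.** Trial pairs share the subject's latent peak
  force perturbed by within-trial noise; the within-SD defaults to
  σ_b √(1/ICC − 1) with σ_b the empirical between-subject SD of a
  fixed-seed calibration cohort (truncation under consistency shifts it
  from the closed-form mixture value) and ICC the 0.863 target. T1/T2 get
  between-subject SDs of 0.05/0.15 s but trial-level SDs of 0.08/0.20 s,
  reproducing the observed pattern of excellent force reliability and poor
  temporal reliability (ICC ≈ 0.27–0.28).
* **Two denominators.** The published tables count 569 completers for
  sarcopenia but 587 assessed for the frailty columns; the generator treats
  the 569 completers as the analysis population and reports frailty
  prevalence out of it, while component percentages use the published group
  sizes (51/536).

What the generator does **not** emulate: real biomechanics (no forward
dynamics, no chair interaction, no multi-repetition tests), device-specific
noise spectra, missing data and self-report measurement error, or the
unknowable joint distribution of the real cohort. Passing tests therefore
demonstrate that the pipeline is correct and well-calibrated *under the
stated generative model*, not that the published discrimination figures
would replicate on new data; with consistency conditioning the benchmark
AUCs come out somewhat higher than the published ones (e.g. grip ≈ 0.91 vs
0.845), and only the orderings are treated as reproduction targets.

## Numerical choices and degenerate inputs

g is fixed at 9.80665 m/s². All tie-breaks are "earliest sample" /
"lowest threshold" for determinism. The ICC errors out on constant
matrices (zero total variance) and on missing cells. Calibration requires
probabilities strictly inside (0,1); values at the boundary are clipped at
1e−10 with a warning, and a zero-variance linear predictor is an error.
Zero-variance model columns are dropped with a warning; single-class
outcomes are errors. All randomness flows from one integer seed per entry
point, with deterministic child seeds for per-subject substreams; runs are
bit-reproducible given the seed.

## Problem sizes used by the test and acceptance suites

The suites run the generator at the study's own scale where the claim
demands it (n = 569, B = 200 for orderings and reliability recovery; 50
repetitions of a pure-noise validation at n = 569; 10⁵ draws for the
closed-form binormal AUC check) and at reduced sizes (n = 60, B = 8) for
structural and determinism checks, chosen to keep the default run brisk
while leaving the statistical assertions well-powered.

## Known limitations

Single-transition traces only (no 5×STS segmentation); no external
validation or decision-curve analysis; the calibration search targets
prevalences only, not the full joint distribution; the gravity-excluded
dialect's onset is intrinsically unstable under noise (documented above);
and optimism-corrected calibration metrics on small resamples can be noisy,
which is why apparent calibration is reported alongside.
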