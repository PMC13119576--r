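---
title: "Quantifying postural sway dynamics and fall history: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying postural sway dynamics and fall history: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(copsway)
```

## The scientific problem

Force-platform posturography summarizes quiet standing by the trajectory of
the center of pressure (CoP) in the anteroposterior (AP) and mediolateral (ML)
directions. Conventional "linear" metrics — mean sway velocity, sway area,
velocity variability — quantify how *much* a person sways. The
loss-of-complexity view of aging argues that what changes with declining
postural control is often not the amount of sway but its *temporal
organization*: healthy control produces structured variability across many
time scales, while impaired control drifts toward either rigid regularity or
unstructured randomness. `copsway` implements both metric families, a
propensity-score-matched comparison of fallers (one or more self-reported
falls in the prior 12 months) against non-fallers, and a multivariate
feature-contribution analysis, so the whole chain from raw CoP series to
group-level conclusions is reproducible and testable.

## Signal preprocessing

Trials are 60-s recordings at 100 Hz (6000 samples) in cm. Each channel is
low-pass filtered with a second-order Butterworth at 20 Hz applied forward and
backward (zero phase, effective fourth order). Edges are handled by odd
reflective padding of `3 * (order + 1)` samples per end — a standard zero-phase
edge treatment. Instantaneous velocity is the first difference of the filtered
signal times the sampling frequency, giving an (N−1)-sample series; all
velocity statistics use that series. Trials whose sample count differs from
`fs × 60 s` by more than one sample are rejected rather than truncated,
because the analysis assumes complete 60-s recordings.

## Magnitude-based metrics

* `velo` — mean planar speed, `mean(sqrt(v_AP^2 + v_ML^2))`, cm/s.
* `area` — 95% confidence ellipse of the (AP, ML) scatter:
  `pi * qchisq(.95, 2) * sqrt(det(cov))`, cm².
* `velo_ap`, `velo_ml` — mean rectified per-axis velocity. The rectified mean
  is used because the signed mean is ~0 for any stationary trial.
* `velo_sd_ap`, `velo_sd_ml` — SD of the signed per-axis velocity (an SD of
  rectified velocity would largely duplicate the rectified mean).
* `mfreq_ap`, `mfreq_ml` — mean rectified velocity divided by mean absolute
  distance from the trial's mean position, per axis (1/s). This is the plain
  ratio; no `2*pi`-style constant is applied. For a sinusoid of frequency `f`
  the ratio equals `2*pi*f` exactly, which the tests verify. An optional
  multiplicative constant is exposed for cross-study comparability.

"Spatial center" is the per-trial, per-axis mean position — the only reading
consistent with a single trajectory-level summary.

## Temporal-structure metrics

**Sway density (`mp3`, `mt3`, `md3`).** For each sample the sway density curve
(SDC) is the time the CoP spends within a 0.3 cm radius of that sample's
position. The 0.3 cm (3 mm) radius is the value the sway-density literature
attaches to the "3"-suffixed indices; it is configurable. The SDC is smoothed
with a zero-phase low-pass at 2.5 Hz before peak picking, because peak
counting on the raw curve is dominated by sample-level noise. MP3 is the mean
peak height (s), MT3 the mean time between successive peaks (s), MD3 the mean
planar distance between the CoP positions at successive peaks (cm). MT3 is
defined as the inter-peak interval (not peak duration); with fewer than two
peaks MT3/MD3 are flagged undefined rather than zero.

**Katz fractal dimension (`fd`).** `log10(n) / (log10(n) + log10(d/L))` with
`n` steps, total path length `L` and maximal excursion from the first point
`d`, computed on the filtered planar trajectory (consistent with the filter
coming first in the processing chain). A straight line gives exactly 1.

**DFA (`alpha_ap`, `alpha_ml`).** Order-1 detrending on the integrated,
demeaned series over ~20 log-spaced box sizes from 10 to N/8 samples, boxes
taken forward and reversed so all samples are used. These are common defaults;
both are configurable. The spectral-synthesis noise generator provides the
oracle: white noise must give alpha ~ 0.5, Brownian motion ~ 1.5, and a synthesized
target alpha must be recovered within ±0.08 on average.

**Stabilogram diffusion (`sda_*`).** Planar mean-square displacement up to
10 s of lag; least-squares lines in *linear* coordinates over 0.1–0.8 s
(short-term) and 2–10 s (long-term), slopes divided by 4 to give
per-axis-equivalent diffusion coefficients; the fitted lines' intersection
defines the critical point (`sda_crit`, `sda_crid`). The window choices follow
the classic open-loop/closed-loop reading of the two regimes and are
configurable. The Ornstein–Uhlenbeck generator supplies the oracle: its MSD is
`4*sigma^2*(1 − exp(−dt/tau))`, so the short-lag slope, long-lag plateau and a
critical time on the order of `tau` are all known in closed form.

**Multiscale entropy (`mse{1,10,40}_{ap,ml}`).** Sample entropy with m = 2 and
r = 0.2 × SD, Chebyshev distance, self-matches excluded. The tolerance is
computed once from the original series and held fixed across scales (the
canonical multiscale-entropy convention). Coarse-graining uses non-overlapping
means. At scale 40 a 6000-sample trial leaves 150 coarse points; when the
match counts are zero the scale is reported as missing, never as 0 — an
entropy of 0 asserts perfect regularity, which absence of matches does not
show. For white noise the scale-1 value has a closed form,
`−log(2*pnorm(0.2/sqrt(2)) − 1) ≈ 2.185`, used as an oracle.

**RQA (`det_*`, `lam_*`).** Per-channel state-space reconstruction: delay from
the first local minimum of the auto mutual information (32-bin histogram
estimator, smoothed over 7 lags before minimum detection because raw
histogram MI wiggles at the bin scale; series whose lag-1 MI sits at the
estimator's bias floor get delay 1, since no lag carries structure), dimension
from false nearest neighbours (rtol = 10, atol = 2, max dimension 10;
reference points strided for speed; the distance-ratio test is skipped when
the neighbour distance is at machine precision, where the ratio is numerical
noise). The recurrence threshold is calibrated by bisection on the pairwise
distance distribution so the recurrence rate hits 5% (accepted band
4.5–5.5%). Determinism and laminarity use minimal line length 2, Euclidean
norm, and a Theiler window equal to the delay. Only DET and LAM are computed,
deliberately restricting the recurrence vocabulary to two interpretable
indices.

## Trial averaging and the feature table

Metrics are computed per trial and averaged within participant × condition; a
metric undefined on some trials is averaged over the trials where it is
defined and flagged missing only when undefined on all. The result is one row
per participant × condition with 28 named metrics.

## Propensity matching and group comparisons

Fall status (≥1 fall in 12 months) is regressed on eight covariates: age, sex,
BMI, ADL level, illness, number of medications, disability, orthosis/
prosthesis use (logistic regression; a weakly ridge-penalized fit with
lambda = 1e-4 on standardized covariates replaces the ML fit under separation,
which small cohorts with binary covariates can produce). Matching is 1:1
nearest neighbour without replacement on the logit propensity score with a
caliper of 0.2 SD of the logit scores, fallers as the treated group (ATT).
Treated units are processed in descending propensity order with ties broken by
record order — the order affects results, so it is pinned and configurable.
Balance is reported as absolute standardized mean differences before/after
matching (Love-plot table). Matched groups are compared per condition × metric
with Welch's t-test, interpreted descriptively without multiplicity correction
(a Benjamini–Hochberg column is emitted as clearly-optional extra output).
Robustness: (a) covariate-adjusted least squares of each metric on group plus
the eight covariates; (b) propensity-quintile stratification with
stratum-size-weighted group differences (quintiles chosen as the standard
stratification granularity; single-group strata are dropped with a warning).

## SHAP under repeated stratified cross-validation

Per condition, a logistic model with standardized predictors and ridge penalty
lambda = 1 (on the scale `−loglik + lambda/2 * ||beta||²`) is fit on each
training fold of a stratified 5-fold × 30-repeat plan (150 splits).
Regularization is required: with ~28 predictors and ~15 fallers an
unpenalized fit is unstable or separable; lambda is exposed as a knob. Feature
attributions are Monte-Carlo (permutation) Shapley values with 64 coalition
draws per feature, background = the training fold only, output on the
predicted-probability scale (link scale available; on the link scale the
linear model's exact Shapley value `beta_j (x_j − mean x_j)` serves as the
convergence oracle). Standardization statistics and Shapley backgrounds come
from the training fold only — the tests include a leakage fixture with an
extreme test-fold outlier. Per split the five features with the largest mean
|SHAP| are recorded; the stability table reports the proportion of splits in
which each feature ranked top-5 (proportions sum to exactly 5). Out-of-fold
predictions are pooled into AUROC/accuracy, reported as exploratory estimates
only. The two visual conditions are analyzed independently.

## The synthetic generator: what it emulates, what it does not

`gen_cop_trial` mixes (i) a planar Ornstein–Uhlenbeck walk — bounded
random-walk sway with stationary SD ~0.35 cm and relaxation time ~1.5 s,
giving the two-regime diffusion structure; (ii) spectrally synthesized
power-law noise with a chosen DFA exponent (exact target spectrum by
construction, which is why spectral synthesis was chosen over ARFIMA-type
recursions); and (iii) an optional sinusoid carrying a chosen fraction of the
variance, the regularity dial for the entropy/recurrence estimators.
`gen_cohort` adds participant records with the eight covariates, engineered
age–fall confounding, fall counts drawn from {1, 2, 3} with probabilities
{0.8, 0.15, 0.05} (recurrent fallers deliberately scarce, exercising the
"falls ≥ 2" sub-count path), binary encodings for ADL/illness/disability/
orthosis, and a small Poisson medication count. Requested group effects are
injected by shifting per-subject generator parameters (periodic fraction for
entropy/recurrence features, noise amplitude for velocity features, spectral
exponent for DFA, sway amplitude for area); the parameter shift per feature-SD
was calibrated once by simulation over the null parameter distribution and
frozen, so realized effects are approximate by design and the tests use
tolerance bands rather than exact values. Eyes-closed trials scale sway
amplitude by 1.3 relative to eyes-open.

What the generator does *not* emulate: inverted-pendulum biomechanics,
foam-surface conditions, nonstationary drifts, or realistic cross-channel
coupling. Passing tests therefore demonstrate estimator and pipeline
correctness on signals with known dynamics — not clinical validity on real
cohorts.

## Numerical choices and degenerate inputs

* Recurrence-rate calibration bisects on the stored off-Theiler distance
  distribution (monotone in the threshold, so bisection always brackets);
  failure to land in 4.5–5.5% raises an error carrying the bisection trace.
* Degenerate trajectories: zero-variance trials give area 0 with a warning,
  Katz FD 1 with a warning, a degenerate SDA flag, and undefined sway-density
  intervals; entropy saturation (zero match counts) propagates as missing.
* Tie-breaks: matching processes equal propensity scores in record order;
  top-5 SHAP ties resolve by the stable feature order.
* Seeding: a single global seed is expanded into per-stage, per-unit sub-seeds
  with a counter-based hash, so enlarging a cohort never reshuffles existing
  subjects; all public generators are bit-reproducible given their seed.

## Problem sizes used by the verification suite

The test suite runs estimator oracles at full 6000-sample scale (DFA, sample
entropy, SDA, recurrence-rate calibration) and uses reduced cohorts
(8–80 subjects, 1000–6000 samples, 1–2 trials per condition) for pipeline-level
checks; the end-to-end demonstration run uses 30 participants, one trial per
condition at 4000 samples with the full 5 × 30 cross-validation plan. These
sizes are the package's own verification choices: they keep the suite fast
while leaving every code path, including the 150-split plan, fully exercised.

## Known limitations

* The AMI/FNN embedding selections use fixed literature-standard settings
  (32 bins, rtol 10, atol 2); pathological signals can defeat any automatic
  embedding choice, which is why the embedding is overridable per call.
* MT3's reading as inter-peak interval (rather than mean peak duration) is a
  pinned interpretation; both appear in the posturography literature.
* Whether SDA lines should be fit in linear or log-log coordinates is not
  settled; linear fits are used, with the windows exposed.
* The realized size of injected cohort effects is approximate (calibration is
  itself an estimate), so parameter-recovery tests assert bands, not points.
* Out-of-fold AUROC/accuracy on small imbalanced cohorts are noisy and are
  reported as exploratory estimates, never as acceptance-grade quantities.
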