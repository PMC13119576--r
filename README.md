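# copsway

Linear and nonlinear center-of-pressure (CoP) sway analysis with
propensity-matched fall-history comparison and cross-validated SHAP feature
attribution.

## Who this is for

Researchers in posturography and fall-risk epidemiology who work with
force-platform quiet-standing recordings: 60-s trials of the CoP trajectory in
the anteroposterior (AP) and mediolateral (ML) directions, sampled at 100 Hz,
plus a participant table with covariates and a 12-month self-reported fall
count (`Falls12m`; faller = at least one fall). The package reproduces a
complete analysis chain on such data — and ships a synthetic signal/cohort
generator with analytically known dynamics, so every estimator and every
pipeline stage can be verified without access to any particular dataset.

## What it computes

**Magnitude metrics** (per trial, after a zero-phase 2nd-order Butterworth
low-pass at 20 Hz; velocity = first difference × fs):

- `velo` — mean planar velocity, `mean(sqrt(v_AP² + v_ML²))` (cm/s)
- `area` — 95% confidence ellipse, `π · χ²₀.₉₅(2) · √(λ₁λ₂)` of the position
  covariance (cm²)
- `velo_ap/ml`, `velo_sd_ap/ml` — rectified mean and signed SD of per-axis
  velocity
- `mfreq_ap/ml` — mean |velocity| / mean |distance from center| (1/s); equals
  `2πf` for a sinusoid of frequency `f`

**Temporal-structure metrics:**

- `mp3`, `mt3`, `md3` — sway-density indices (0.3 cm radius): mean peak height,
  inter-peak interval, inter-peak CoP distance
- `fd` — Katz fractal dimension `log n / (log n + log(d/L))` of the planar path
- `alpha_ap/ml` — DFA scaling exponents (order-1 detrend, log-spaced boxes)
- `sda_ds`, `sda_dl`, `sda_crit`, `sda_crid` — stabilogram-diffusion short/long
  coefficients (planar MSD slopes / 4) and the critical point between regimes
- `mse1/10/40_ap/ml` — multiscale sample entropy (m = 2, r = 0.2 SD, fixed
  across scales)
- `det_ap/ml`, `lam_ap/ml` — RQA determinism and laminarity with AMI-selected
  delay, FNN-selected dimension, and the recurrence threshold calibrated so
  the recurrence rate is 5%

**Statistics:** logistic propensity scores on eight covariates (age, sex, BMI,
ADL, illness, medications, disability, orthosis), 1:1 nearest-neighbor
matching without replacement within a 0.2-SD logit caliper (fallers = treated,
ATT), standardized-mean-difference balance tables, Welch comparisons of the
matched groups, covariate-adjusted and PS-quintile-stratified sensitivity
analyses, and Monte-Carlo (permutation) Shapley attribution of a standardized
ridge-logistic fall-history model under stratified 5-fold × 30-repeat
cross-validation (150 splits per visual condition), with training-fold-only
standardization and SHAP backgrounds, and top-5 ranking stability as the
summary.

## Worked example

```r
library(copsway)

# a synthetic cohort: 12 fallers / 24 non-fallers, engineered age confounding,
# and a -0.8 SD deficit injected into scale-1 ML sample entropy of fallers
coh <- gen_cohort(synth_cohort_params(
  n_fallers = 12, n_nonfallers = 24, confound_strength = 0.8,
  effect_features = c(mse1_ml = -0.8), trials_per_condition = 1,
  n_samples = 3000, seed = 42))

sel <- select_cohort(coh$records, coh$trials)
#> <cohort_selection> 12 fallers, 22 non-fallers (3 recurrent); 68 trials; 2 excluded

feats <- extract_features(sel$trials,
                          metrics = c("velo", "area", "mse1_ml", "alpha_ap"),
                          control = nl_control(mse_scales = 1))
head(feats[feats$condition == "EO_firm", ], 3)
#>    participant_id condition velo area mse1_ml alpha_ap
#> 35           S001   EO_firm 3.78 2.07   0.328     1.45
#> 36           S002   EO_firm 4.96 2.47   0.419     1.37
#> 37           S003   EO_firm 3.76 1.98   0.249     1.41

fit <- fit_propensity(sel$records)
m <- nn_caliper_match(fit)
m
#> <cop_match> 8 pairs (caliper 0.2455 logit units), 4 treated unmatched

head(smd_table(sel$records, m), 3)
#>   covariate smd_before smd_after
#> 1       age       0.62    0.1183
#> 2       sex       0.34    0.0000
#> 3       bmi       0.31    0.0066

w <- welch_compare(feats, sel$records, m)
subset(w, condition == "EO_firm", c(metric, mean_faller, mean_nonfaller, t, p))
#>     metric mean_faller mean_nonfaller       t     p
#> 5     velo       5.175          5.241 -0.1160 0.909
#> 6     area       2.667          2.676 -0.0171 0.987
#> 7  mse1_ml       0.346          0.425 -1.1372 0.287
#> 8 alpha_ap       1.354          1.358 -0.1537 0.880
```

Reading the output: two participants drew ages below the 60-year eligibility
cut and were excluded; matching kept 8 of 12 fallers and cut the age imbalance
from 0.62 to 0.12 SD; the injected entropy deficit shows up as a lower faller
mean (0.346 vs 0.425 nats) that this small matched sample cannot resolve
(p = 0.287) — magnitude metrics sit on top of each other, as constructed.

`run_full(run_config(...))` chains all stages (simulate/load → select →
extract → match → SHAP-CV) and writes the report tables (features, Love-plot
SMDs, Welch comparisons, sensitivity analyses, matched pairs, per-condition
SHAP stability and beeswarm tables) plus a run manifest recording every count
and exclusion. A thin command-line front end with `simulate`, `extract`,
`match`, `analyze` and `run` subcommands is in
`inst/scripts/copsway-cli.R`.

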