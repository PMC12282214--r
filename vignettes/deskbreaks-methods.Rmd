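---
title: "Methods: simulating and analyzing a workplace active-break study"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing a workplace active-break study}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

deskbreaks re-implements, as a tested pipeline, the analysis of a one-year
quasi-experimental workplace intervention that introduced short active
breaks from prolonged sitting: accelerometer epoch streams are reduced to
occupational sedentary-behavior (SB) and physical-activity (PA) metrics,
self-report scales are scored, missing data are multiply imputed, and the
one-year change in each outcome is compared between a 172-worker
intervention arm and a 323-worker control arm by propensity-score overlap
weighting. Because no participant data are released for such studies, the
package ships a calibrated synthetic cohort generator, and the package's
own validation is parameter recovery: the analysis pipeline must re-find
the effects the generator was programmed with.

This vignette records the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic validation does
and does not establish.

## The estimand and the weighting model

For each outcome the analysis variable is the individual change score
$Y_i = X_i^{\text{follow-up}} - X_i^{\text{baseline}}$. Group membership
$Z_i$ (1 = intervention) is not randomized: controls are older, more often
male and managerial, and more sedentary. A logistic propensity model
$e(x) = \Pr(Z = 1 \mid x)$ is fitted per outcome on age, sex, BMI, job
position and that outcome's baseline value. Overlap weights

$$w_i = Z_i\,(1 - e_i) + (1 - Z_i)\,e_i$$

target the average treatment effect in the overlap population (ATO),
estimated by the Hájek contrast of weighted arm means
$\hat\tau = \bar Y^w_1 - \bar Y^w_0$. Overlap weights have two properties
the package asserts numerically on every analysis: weights lie in (0, 1)
with no trimming, and — with a maximum-likelihood logistic fit — the
weighted means of every covariate in the model agree between arms exactly
(to solver tolerance), which the test suite checks at $10^{-8}$.

Standard errors come from the M-estimation sandwich $A^{-1} B A^{-\top}$
over the stacked estimating equations (logistic scores plus the two
weighted-mean equations), so the uncertainty from estimating the
propensity scores propagates into the variance. Whether the original
analysis stacked the score equations or held the weights fixed is not
derivable from the published description; both are implemented
(`variance = "stacked"` / `"fixed"`), stacked being the default because it
is the standard asymptotics for estimated overlap weights. Single-dataset
inference uses the normal reference; after multiple imputation the usual
t reference with the classic Rubin degrees of freedom
$(m-1)\,(1 + W/((1+1/m)B))^2$ applies. The fit itself is `stats::glm`
followed by Newton polishing until the score norm
$\max_j |X^\top(z - e)|_j < 10^{-8}$, which is what makes the exact-balance
identity hold to numerical precision; degenerate fitted probabilities
(within $10^{-10}$ of 0/1) are treated as separation and raised as errors,
never clipped.

Per-outcome propensity models (each including its own baseline value) mean
each outcome has its own weights; this follows the wording of the source
analysis and is worth knowing when comparing balance reports across
outcomes. The within-arm "post − pre" rows of the results table are the
overlap-weighted arm means of the change scores; whether the original
tables used weighted arm means or a model decomposition is not stated, and
the weighted-arm-mean reading is used throughout. Descriptive pre/post
columns are computed on observed cases only. Two-sided 5% significance,
no multiplicity correction.

## Accelerometer processing rules

One record per 60-s epoch with a MET value; the working window is the
half-open clock interval [09:00, 17:00), i.e. 480 epoch slots, an epoch
belonging to the window iff its start time does.

* **Classification.** SB for MET in (0, 1.5], light activity (LPA) in
  (1.5, 3.0), MVPA at or above 3.0. The printed cut-points ("≤1.5",
  "1.6–2.9") leave a nominal gap at (1.5, 1.6) on a 0.1-resolution device;
  the half-open convention closes it so every value classifies.
* **Non-wear.** Maximal runs of at least 60 consecutive below-detection
  (MET = 0) epochs; shorter zero runs are wear, with no tolerance epochs
  inside a run. Worn zero epochs are counted as sedentary — motionless
  sitting is below the detection limit — which preserves the identity
  worn SB + LPA + MVPA = wear time.
* **Valid day.** Wear time at least 75% of the window (360 min); subjects
  need at least 4 valid days, otherwise their behavior metrics are set
  missing and flow into the imputation stage (the record is kept).
* **Bouts.** Prolonged SB: unbroken worn SB runs of 30+ min (count and
  total time). Bouted PA: unbroken worn activity runs of 3–10 min,
  LPA and MVPA mixing freely within a run ("continued PA" is not
  intensity-specific). Runs longer than 10 min are excluded entirely by
  default, reading "from 3 to 10 minutes" as a band-pass; because
  truncating them at 10 min is an equally defensible reading, both are
  available (`pa_long_runs = "exclude"` / `"truncate"`).
* **Standardization.** Every behavior quantity — minutes, bout counts,
  steps — is scaled by 480 / wear-minutes to an 8-hour workday, then
  averaged over valid days. Standardized SB + LPA + MVPA is exactly 480
  for every valid day, a conservation identity the test suite asserts at
  $10^{-9}$.

## The synthetic cohort generator

The generator is first-class, tested code; its defaults are the study
conditions, chosen once from the published baseline table and effect
estimates.

**Covariates.** Arms are drawn directly from per-arm marginals (age
45.3 ± 11.6 vs 51.6 ± 7.2; women 92.4% vs 56.3%; BMI 21.9 ± 3.3 vs
23.3 ± 4.4; managers 14.1% vs 28.2%), which guarantees exact arm sizes and
the published between-arm contrasts; by Bayes' rule this is equivalent to
a confounded assignment model. A `confounding` multiplier interpolates
every arm parameter toward the pooled population (log-odds scale for
binary covariates), so 0 gives exchangeable arms for null-calibration
studies. An explicit latent-index assignment model (sampling membership
probabilities and thresholding) was considered and rejected: it needs
per-covariate calibration to hit the published arm means, which the
direct parameterization satisfies by construction.

**Epoch streams.** Wear-time behavior is a first-order Markov chain over
{SB, LPA, MVPA} built as `P = c · 1πᵀ + (1 − c) I`: its stationary law is
exactly the target occupancy π for any mixing rate c in (0, 1], while c
sets dwell times (geometric runs with continuation probability
1 − c(1 − π_i)). Per-arm mixing comes from the SB persistence parameter
(defaults 0.895 intervention / 0.910 control), calibrated so baseline
prolonged-SB time lands near the published 64 and 115 min/8 h; the
approach-specific geometric formula underestimates bout time because
subjects with above-average SB occupancy sit in longer runs, so the
defaults were set against the simulated pipeline rather than the
closed form. MET emissions: SB uniform on the 0.9–1.5 grid, LPA on
1.6–2.9, MVPA 3.0 + exponential (mean 0.5), all at 0.1 resolution;
non-wear is MET 0. Steps are Poisson with intensity proportional to MET
during activity epochs and zero otherwise, the per-MET rate calibrated so
standardized steps match the published arm means at baseline and the
programmed change at follow-up. Device-off time is one contiguous block
per day of 60–110 min (at least 60 so the non-wear detector can find it)
with per-arm probability solved from the published mean wear times
(442.8 / 478.9 min). Wear-day counts are normal draws (4.7 ± 0.5 /
12.2 ± 4.5, floored at 4).

**Subject profiles and effects.** Each subject's standardized-minute
triple is the arm profile plus a sum-zero Gaussian deviation (the
sum-zero constraint fixes one covariance; the SB/LPA/MVPA deviation SDs
default to 58/52/12 intervention, 52/48/12.5 control), floored at zero
with the deficit taken from the largest component so every latent triple
sums to exactly 480. Follow-up adds the programmed arm effect plus
sum-zero change noise (SDs 35/30/10 min/8 h). Because measured behavior
changes must also sum to zero, a published change triple that does not
(−24.4, +12.6, +10.1 sums to −1.7 through rounding and estimation) cannot
be realized by any generator; `conserved_changes()` projects the
requested triple onto the sum-zero simplex, allocating the residual
proportionally to each change's magnitude (−23.52, +13.06, +10.47 at the
defaults, each within 4% of the requested value). The projected values
are the generator's programmed truth and the recovery targets.

**Questionnaires.** Latent scale scores: psychological distress (K6,
0–24) uses gamma marginals (right-skewed, non-negative, a realistic mass
of zeros); engagement (0–6 item mean) and presenteeism (0–10) use normal
marginals. Follow-up is generated conditionally on baseline with an
independent individual change: normal additive for the normal scales, and
for the gamma scale a conditional gamma with mean baseline + Δ, so the
conditional mean change equals the programmed effect at *every* baseline
value. This matters: the weights depend on the baseline score, so any
regression-to-the-mean in the generator (e.g. a correlated-marginals
copula) would make the weighted within-arm mean change differ from the
programmed Δ — a generator artifact, not an estimator failure. Change
SDs are derived as $\sqrt{\mathrm{sd_{fu}}^2 - \mathrm{sd_b}^2}$ from the
published pre/post SDs. Latents are discretized to the scale lattice and
decomposed into item vectors (6 K6 items 0–4, 9 engagement items 0–6)
whose standard scoring reproduces the discretized score exactly; values
outside the range are clamped with a counted warning. Item-level scoring
follows the published scale definitions (sum for K6, item mean for
engagement, identity for presenteeism); any missing item makes the score
missing, with no prorating, matching how whole-score missing counts are
reported in the source table.

**Missingness.** Missing at random: deletion probability is logistic in
standardized age (slope −0.4) and sex (slope +0.3) with the intercept
solved per arm and variable to hit the configured expected rate (rates
default to the published per-variable missing counts, e.g. 28/172 and
17/323 for the accelerometer). Age and sex themselves use rate-only
deletion to keep the mechanism well-defined. Accelerometer missingness
removes the whole subject-visit epoch stream (a device-level failure);
questionnaire missingness blanks all items of an instrument at a visit;
adherence recalls are blanked per time point at 5.5% so roughly 145 of
172 intervention subjects remain complete at all three recalls.
Follow-up attrition defaults to zero because the published arms are
completer samples. MNAR mechanisms are out of scope: the downstream
imputation assumes MAR.

**Tabular mode.** `epoch_mode = "tabular"` draws subject-level behavior
summaries directly (latent profile plus day-averaged measurement noise,
with day-to-day SDs of 23/22/10.5 min for SB/LPA/MVPA matched to the
epoch model's empirical within-subject variation) and skips epoch
streams; it exists for large simulation studies (type-I error, CI
coverage at 500 replicates) where epoch volume would dominate runtime.
Bout metrics are not available in this mode and are dropped from the
outcome list.

## Imputation

Multiple imputation by chained equations with predictive mean matching,
written against the standard algorithm: for each incomplete variable, a
Bayesian linear regression on all other analysis variables (observed
cases), a posterior draw of coefficients and residual variance, type-1
matching (posterior-draw predictions for missing cases against
least-squares predictions for donors), and a uniform draw among the
`k_donors = 5` nearest donors, whose *observed* value is copied — so
imputations always stay within each variable's observed support,
including 0/1 codings. Ten sweeps per dataset, `m = 20` datasets,
analyzed individually and pooled by Rubin's rules. Donor count and sweep
count are conventional defaults; the method description fixes only the
algorithm family and m.

One structural point required care. The analysis variables satisfy exact
linear identities (baseline SB + LPA + MVPA = 480; the three behavior
changes sum to 0). If a complete dependent set enters the chained
equations, a jointly missing triple is anchored only by its own current
imputations — the regression of any one on the other two is exact — and
drifts to arbitrary self-consistent values, badly biasing the arm means.
The pipeline therefore imputes a non-redundant set (SB and LPA columns)
and reconstructs MVPA from the identities afterwards. Rank-deficient
predictor matrices are handled by pivoted-QR column dropping.

The imputation model includes group, all covariates and all outcome
columns (baseline and change); the source description does not state the
predictor set, and "all other analysis variables" is the conventional
default. With zero missingness the whole MI pipeline reproduces the
complete-case analysis exactly (per-imputation analyses are identical, so
the between-imputation variance is 0), which the test suite asserts.

## Numerical choices and degenerate inputs

* Propensity fitting: IRLS (via `glm`) to epsilon $10^{-12}$, Newton
  polish to score norm $10^{-8}$, 100-iteration cap; separation and
  singular sandwich bread matrices are errors with diagnostics, not
  warnings.
* Negative MET values, gapped epoch sequences, out-of-range item values,
  missingness rates outside [0, 1], arm sizes below 2 and empty outcome
  lists are rejected at the interface.
* Zero wear time makes standardized metrics missing rather than infinite;
  an empty window intersection returns an empty stream, not an error.
* All randomness flows from one seed per entry point; stage sub-seeds are
  derived deterministically and kept within the 32-bit integer range.
  Identical seed and configuration give bitwise-identical outputs.

## What the validation shows — and what it cannot

The recovery studies run the full pipeline on 100 synthetic cohorts at
the study's arm sizes with 5 measured workdays per subject per visit (a
problem size chosen to keep the Monte-Carlo study tractable; wear-day
counts are a config field) and require the mean estimate to sit within
2 Monte-Carlo standard errors of the generator's programmed value; the
baseline-calibration, adherence, type-I (500 tabular replicates),
coverage, exact-balance, bout-oracle and bootstrap-agreement checks run
alongside. The type-I and coverage study measures behavior over many
days so the baseline entering the propensity model is essentially free
of measurement error: with a noisy baseline, the measured-change
estimand is not zero even when the true effect is (regression to the
mean through baseline adjustment) — a well-known property of pre–post
designs with error-laden baselines, and one this package's synthetic
studies make visible rather than a defect of the estimator. At the
recovery harness's five measured days the residual effect is small
relative to Monte-Carlo error; analysts of real cohorts should note it
when wear protocols are short. Passing them shows the pipeline implements the stated rules
and estimators correctly and recovers known effects under the generator's
assumptions: first-order wear-state dynamics, MAR missingness,
homogeneous arm effects, independent individual changes. Real cohorts
violate several of these (day-of-week structure, MNAR dropout,
effect heterogeneity, device artifacts beyond a single off-block), so the
validation certifies the software, not the original study's substantive
conclusions; with observed data the package reproduces the published
analysis choices, including their limitations (a small covariate set and
outcome-specific weights among them).

## Known limitations

* The generator emits work-window epochs only; control-arm full-day wear
  is summarized by the same window, and full-day emission would be an
  extension.
* Step counts at follow-up are calibrated in mean only; their
  distributional change is not modeled.
* Categorical covariates are imputed through PMM on their numeric coding,
  adequate at the low missingness rates emulated but not a general
  categorical imputation model.
* Prolonged-SB and bouted-PA effects are emergent (occupancy shifts under
  fixed persistence), not separately programmable; the published bout
  changes are therefore not recovery targets.
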