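# deskbreaks

Office workers accumulate most of their sitting time at work, and
workplace programs that insert short active breaks into the work schedule
are a low-cost way to reduce it. Evaluating such programs is rarely
randomized: intervention and control arms come from different offices and
differ in age, sex, job position and baseline sitting. `deskbreaks`
implements the full analysis pipeline for this kind of one-year
quasi-experimental pre–post study, together with a calibrated synthetic
cohort generator so every stage is testable without participant data.

The pipeline covers:

* **Accelerometer epoch processing** — 60-s epochs classified by MET
  cut-points (sedentary ≤ 1.5, light 1.6–2.9, moderate-to-vigorous ≥ 3.0),
  non-wear detection (60-min below-detection runs), the 09:00–17:00
  working window, ≥ 75% valid-day and ≥ 4 valid-day rules, prolonged
  sitting bouts (≥ 30 min) and bouted activity (3–10 min runs), all
  standardized to an 8-hour workday
  (`standardized = observed × 480 / wear minutes`).
* **Questionnaire scoring** — K6 psychological distress (sum, 0–24),
  work-engagement item mean (0–6), single-item absolute presenteeism
  (0–10), and a 4-level program-adherence recall at three time points.
* **Multiple imputation** — chained equations with predictive mean
  matching (type-1, 5-donor), m = 20 datasets, Rubin's-rule pooling.
* **Causal contrast** — per-outcome logistic propensity scores on age,
  sex, BMI, job position and the outcome's baseline value; overlap
  weights `w = Z(1−e) + (1−Z)e` targeting the average treatment effect in
  the overlap population (ATO); Hájek within-arm mean changes and their
  contrast; M-estimation sandwich variance with the propensity-score
  equations stacked in.

For the weighted contrast of change scores the package estimates

```
τ̂ = Σ wᵢZᵢYᵢ / Σ wᵢZᵢ − Σ wᵢ(1−Zᵢ)Yᵢ / Σ wᵢ(1−Zᵢ),   wᵢ = Zᵢ(1−eᵢ) + (1−Zᵢ)eᵢ
```

with `Var(τ̂)` from `A⁻¹BA⁻ᵀ` over the stacked estimating equations.
Overlap weights balance every covariate in the propensity model exactly
(to solver tolerance), which the package asserts on each run.

## Worked example

A scaled-down synthetic study end to end (simulate → epoch processing →
score → impute → weight → pool):

```r
library(deskbreaks)

cfg <- study_config(
  cohort = cohort_config(n_intervention = 80, n_control = 120, seed = 2024),
  imputation = imputation_spec(m = 5),
  outcomes = c("sb", "lpa", "mvpa", "k6"),
  seed = 2024)
report <- run_study(cfg)
print(report)
#> Synthetic workplace active-break study report
#>   arms: 80 intervention / 120 control, 5 imputations, seed 2024
#>
#> Overlap-weighted (ATO) results:
#>   sb     change int  -22.40 (-33.26, -11.55)  ctl  13.26  diff  -35.66 (-50.15, -21.17) p=3.37e-06
#>   lpa    change int   11.30 (2.07, 20.52)     ctl -14.79  diff   26.09 (13.02, 39.15)   p=0.000139
#>   mvpa   change int   10.70 (6.66, 14.75)     ctl   1.80  diff    8.90 (4.14, 13.66)    p=0.000269
#>   k6     change int    1.39 (0.93, 1.85)      ctl  -0.04  diff    1.43 (0.92, 1.94)     p=5.34e-08
```

Each row is one outcome: the pooled overlap-weighted within-arm change
with its 95% CI for the intervention arm, the control-arm change, and the
ATO group difference with CI and p-value. In this cohort the generator
was programmed with a sedentary-time reduction near −24 min/8 h and
compensating activity increases; the pipeline recovers them within
sampling error, and the distress score (K6) rises by ~1.4 points in the
intervention arm, mirroring the adverse secondary effect this design
emulates. The balance report shows what the weighting buys:

```r
subset(report$balance, outcome == "sb",
       c(covariate, smd_unweighted, smd_weighted))
#>  covariate smd_unweighted  smd_weighted
#>        age     -0.6727714 -1.329248e-14
#>        sex      0.8597039  2.316450e-14
#>        bmi     -0.3442853 -7.200812e-15
#>    manager     -0.4953168 -3.055599e-14
#>       sb_b     -0.3215925 -8.838413e-15
```

Substantial unweighted imbalance (|SMD| up to 0.86), exact balance after
overlap weighting. `report$baseline` holds the two-group baseline table,
`report$adherence` the complete-case adherence shares, and
`report$complete_case` the sensitivity analysis.

The full-size default configuration (`cohort_config()` with no
arguments) reproduces the 172/323-worker cohort with confounded arms,
published baseline calibration and missing-data pattern.

A thin command-line front end over the same functions lives at
`inst/cli/deskbreaks.R` (`simulate`, `process-accel`, `run` subcommands,
YAML configuration via `read_study_config()`).

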