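#' Cohort generator configuration
#'
#' Builds the configuration object that defines the synthetic two-arm cohort:
#' arm sizes, confounded covariate distributions, occupational behavior
#' profiles (standardized minutes per 8-hour workday), wear structure,
#' questionnaire latent models, missingness rates, and adherence
#' probabilities. Defaults reproduce the baseline characteristics of a
#' 172-worker intervention arm and a 323-worker control arm from a one-year
#' workplace active-break study: controls are older, more often male and
#' managerial, and more sedentary than intervention workers.
#'
#' Behavior profiles are expressed as mean/SD of standardized minutes
#' (minutes per 480 wearing minutes) of sedentary behavior (SB),
#' light-intensity physical activity (LPA) and moderate-to-vigorous physical
#' activity (MVPA); internally they are converted to occupancy fractions of
#' a first-order Markov chain over wear states. `sb_persist` is the
#' per-epoch probability that an SB epoch is followed by another SB epoch;
#' it controls sitting-bout lengths and is calibrated so prolonged-SB time
#' (bouts of 30 minutes or more) is about 64 min/8 h in the intervention arm
#' and 115 min/8 h in the control arm at baseline.
#'
#' @param n_intervention,n_control arm sizes (each at least 2).
#' @param seed integer seed used by [simulate_cohort()].
#' @param confounding scalar in `[0, 1]` scaling the between-arm covariate
#'   differences: 1 reproduces the study's confounded assignment, 0 makes
#'   the two arms exchangeable.
#' @param covariates list with per-arm age mean/SD, proportion female, BMI
#'   mean/SD and proportion managerial (see defaults).
#' @param behavior list with per-arm baseline standardized-minute means and
#'   between-subject SDs for SB/LPA/MVPA, wear time means, and SB
#'   persistence probabilities.
#' @param behavior_change_sd subject-level SD (min/8 h) of the follow-up
#'   minus baseline change in each behavior, before sum-zero centering.
#' @param wear_days list of per-arm mean/SD of the number of measured
#'   workdays per visit (truncated below at `min_days`).
#' @param nonwear_block range (minutes) and per-day probability, per arm, of
#'   a contiguous device-off block inside the work window; blocks are at
#'   least 60 min so the non-wear detector can find them.
#' @param steps_baseline per-arm mean standardized step count used to
#'   calibrate the per-MET Poisson step rate of PA epochs.
#' @param questionnaires latent-scale models per instrument and arm:
#'   baseline mean/SD and follow-up SD; the SD of the individual change is
#'   derived as `sqrt(fu_sd^2 - sd^2)` (so follow-up SDs must be at least
#'   the baseline SDs for a stochastic change).
#' @param mvpa_excess mean of the shifted-exponential MET excess above 3.0
#'   for MVPA epochs.
#' @param missingness per-variable, per-arm missingness probabilities
#'   (missing at random, driven by age and sex), plus `attrition` (whole
#'   follow-up record removal) and `adherence` (per recall point).
#' @param adherence list with `p_always` (top-category probability at the
#'   three recall points) and `rest_split` (how the remainder is divided
#'   over the other three categories).
#' @param work_window character vector `c(start, end)` clock times; the
#'   half-open window `[start, end)` defines the workday (default 480
#'   one-minute epochs).
#' @param epoch_mode `"markov"` simulates full epoch streams; `"tabular"`
#'   draws subject-level behavior summaries directly from the latent model
#'   (no epoch data), for large simulation studies.
#' @param min_days lower truncation for wear-day counts.
#'
#' @return an object of class `cohort_config` (a validated list).
#' @export
#' @examples
#' cfg <- cohort_config(n_intervention = 20, n_control = 30, seed = 1)
#' cfg$behavior$intervention$profile
cohort_config <- function(n_intervention = 172,
                          n_control = 323,
                          seed = 1L,
                          confounding = 1,
                          covariates = list(
                            age = list(intervention = c(45.3, 11.6),
                                       control      = c(51.6, 7.2)),
                            p_female = c(intervention = 0.924, control = 0.563),
                            bmi = list(intervention = c(21.9, 3.3),
                                       control      = c(23.3, 4.4)),
                            p_manager = c(intervention = 0.141, control = 0.282)
                          ),
                          behavior = list(
                            intervention = list(
                              profile = c(sb = 308.1, lpa = 149.8, mvpa = 23.1),
                              sd      = c(sb = 58,   lpa = 52,   mvpa = 12),
                              wear_mean = 442.8,
                              sb_persist = 0.895
                            ),
                            control = list(
                              profile = c(sb = 341.4, lpa = 116.0, mvpa = 23.7),
                              sd      = c(sb = 52,   lpa = 48,   mvpa = 12.5),
                              wear_mean = 478.9,
                              sb_persist = 0.910
                            )
                          ),
                          behavior_change_sd = c(sb = 35, lpa = 30, mvpa = 10),
                          wear_days = list(intervention = c(4.7, 0.5),
                                           control = c(12.2, 4.5)),
                          nonwear_block = list(length = c(60, 110),
                                               prob = NULL),
                          steps_baseline = c(intervention = 3834.5,
                                             control = 3597.2),
                          questionnaires = list(
                            k6 = list(range = c(0, 24), items = 6, item_max = 4,
                                      family = "gamma",
                                      intervention = c(mean = 5.1, sd = 5.2,
                                                       fu_sd = 5.6),
                                      control      = c(mean = 3.1, sd = 4.0,
                                                       fu_sd = 4.2)),
                            uwes = list(range = c(0, 6), items = 9, item_max = 6,
                                        family = "normal",
                                        intervention = c(mean = 2.2, sd = 0.9,
                                                         fu_sd = 1.0),
                                        control      = c(mean = 2.9, sd = 1.5,
                                                         fu_sd = 1.53)),
                            hpq = list(range = c(0, 10), items = 1, item_max = 10,
                                       family = "normal",
                                       intervention = c(mean = 5.0, sd = 1.3,
                                                        fu_sd = 1.5),
                                       control      = c(mean = 6.1, sd = 1.6,
                                                        fu_sd = 1.7))
                          ),
                          mvpa_excess = 0.5,
                          missingness = list(
                            age     = c(intervention = 6 / 172,  control = 0),
                            sex     = c(intervention = 2 / 172,  control = 0),
                            bmi     = c(intervention = 17 / 172, control = 0),
                            manager = c(intervention = 2 / 172,  control = 0),
                            accel   = c(intervention = 28 / 172, control = 17 / 323),
                            k6      = c(intervention = 3 / 172,  control = 2 / 323),
                            uwes    = c(intervention = 3 / 172,  control = 8 / 323),
                            hpq     = c(intervention = 4 / 172,  control = 1 / 323),
                            attrition = c(intervention = 0, control = 0),
                            adherence = 0.055
                          ),
                          adherence = list(
                            p_always = c(0.621, 0.586, 0.669),
                            rest_split = c(0.15, 0.35, 0.50)
                          ),
                          work_window = c("09:00", "17:00"),
                          epoch_mode = c("markov", "tabular"),
                          min_days = 4L) {
  epoch_mode <- match.arg(epoch_mode)

  if (n_intervention < 2 || n_control < 2)
    stop("arm sizes must be at least 2", call. = FALSE)
  if (confounding < 0 || confounding > 1)
    stop("`confounding` must be in [0, 1]", call. = FALSE)

  for (arm in c("intervention", "control")) {
    b <- behavior[[arm]]
    if (any(b$profile < 0) || any(b$sd < 0))
      stop("behavior profile means and SDs must be non-negative", call. = FALSE)
    if (b$wear_mean <= 0)
      stop("wear_mean must be positive", call. = FALSE)
    if (b$sb_persist <= 0 || b$sb_persist >= 1)
      stop("sb_persist must be in (0, 1)", call. = FALSE)
  }

  win <- parse_window(work_window)
  if (win[2] - win[1] < 1)
    stop("work window must contain at least one 60-s epoch", call. = FALSE)

  for (v in names(missingness)) {
    r <- missingness[[v]]
    if (any(r < 0) || any(r > 1))
      stop("missingness rate for '", v, "' outside [0, 1]", call. = FALSE)
  }

  if (length(adherence$p_always) != 3L ||
      any(adherence$p_always < 0) || any(adherence$p_always > 1))
    stop("adherence$p_always must be three probabilities", call. = FALSE)
  if (abs(sum(adherence$rest_split) - 1) > 1e-8)
    stop("adherence$rest_split must sum to 1", call. = FALSE)

  # per-day probability of a device-off block, from the wear-time deficit
  if (is.null(nonwear_block$prob)) {
    mean_block <- mean(nonwear_block$length)
    window_len <- win[2] - win[1]
    nonwear_block$prob <- vapply(c("intervention", "control"), function(arm) {
      min(1, max(0, (window_len - behavior[[arm]]$wear_mean) / mean_block))
    }, numeric(1))
  }

  structure(list(
    n_intervention = as.integer(n_intervention),
    n_control = as.integer(n_control),
    seed = as.integer(seed),
    confounding = confounding,
    covariates = covariates,
    behavior = behavior,
    behavior_change_sd = behavior_change_sd,
    wear_days = wear_days,
    nonwear_block = nonwear_block,
    steps_baseline = steps_baseline,
    questionnaires = questionnaires,
    mvpa_excess = mvpa_excess,
    missingness = missingness,
    adherence = adherence,
    work_window = work_window,
    window_min = win,
    epoch_mode = epoch_mode,
    min_days = as.integer(min_days)
  ), class = "cohort_config")
}

#' Programmed intervention effects
#'
#' True within-arm mean changes (follow-up minus baseline) per outcome that
#' the generator applies. Defaults are the published one-year changes:
#' the intervention arm reduces occupational sedentary time by 24.4 min/8 h
#' while light and moderate-to-vigorous activity rise by 12.6 and 10.1
#' min/8 h, steps rise by ~1180/8 h, psychological distress worsens by +1.6
#' points, work engagement declines by 0.1 points and job performance rises
#' by 0.2 points; the control arm changes little.
#'
#' Because standardized SB/LPA/MVPA minutes sum to 480 on every valid day,
#' only sum-zero behavior-change triples are physically realizable; the
#' generator therefore applies [conserved_changes()] of these values.
#'
#' @param intervention,control named numeric vectors of mean changes; names
#'   must include `sb`, `lpa`, `mvpa` (min/8 h), `steps` (steps/8 h), `k6`,
#'   `uwes`, `hpq` (scale points).
#' @return object of class `true_effects`.
#' @export
#' @examples
#' true_effects()$intervention
true_effects <- function(intervention = c(sb = -24.4, lpa = 12.6, mvpa = 10.1,
                                          steps = 1179.8,
                                          k6 = 1.6, uwes = -0.1, hpq = 0.2),
                         control = c(sb = 1.4, lpa = -2.1, mvpa = 0.5,
                                     steps = 8.3,
                                     k6 = 0.1, uwes = 0.1, hpq = 0.4)) {
  need <- c("sb", "lpa", "mvpa", "steps", "k6", "uwes", "hpq")
  for (v in list(intervention, control))
    if (!all(need %in% names(v)))
      stop("effects must name: ", paste(need, collapse = ", "), call. = FALSE)
  structure(list(intervention = intervention, control = control),
            class = "true_effects")
}

#' Time-conserving projection of behavior changes
#'
#' Standardized SB + LPA + MVPA minutes equal 480 on every valid day, so the
#' within-arm mean changes of the three behaviors must sum to zero. Printed
#' study estimates need not (rounding, imputation, weighting); this helper
#' projects a requested `(sb, lpa, mvpa)` change triple onto the sum-zero
#' simplex by allocating the residual proportionally to the absolute size of
#' each change. These are the changes the generator actually realizes and
#' the values parameter-recovery checks target.
#'
#' @param effects a [true_effects()] object.
#' @return `true_effects` object whose behavior components sum to zero per
#'   arm (other outcomes unchanged).
#' @export
#' @examples
#' conserved_changes(true_effects())$intervention[c("sb", "lpa", "mvpa")]
conserved_changes <- function(effects = true_effects()) {
  beh <- c("sb", "lpa", "mvpa")
  for (arm in c("intervention", "control")) {
    d <- effects[[arm]][beh]
    r <- sum(d)
    tot <- sum(abs(d))
    adj <- if (tot > 0) d - r * abs(d) / tot else d - r / length(d)
    # absorb floating residual in the largest component
    adj[which.max(abs(adj))] <- adj[which.max(abs(adj))] - sum(adj)
    effects[[arm]][beh] <- adj
  }
  effects
}

#' Chained-equation imputation settings
#'
#' @param m number of imputed datasets (default 20).
#' @param n_iterations chained-equation sweeps per dataset.
#' @param k_donors donor-pool size for predictive mean matching.
#' @param seed integer RNG seed.
#' @return object of class `imputation_spec`.
#' @export
imputation_spec <- function(m = 20L, n_iterations = 10L, k_donors = 5L,
                            seed = 1L) {
  if (m < 2) stop("m must be at least 2", call. = FALSE)
  if (k_donors < 1) stop("k_donors must be at least 1", call. = FALSE)
  if (n_iterations < 1) stop("n_iterations must be at least 1", call. = FALSE)
  structure(list(m = as.integer(m), n_iterations = as.integer(n_iterations),
                 k_donors = as.integer(k_donors), seed = as.integer(seed)),
            class = "imputation_spec")
}

#' Full study configuration
#'
#' Bundles the cohort generator settings, programmed effects, imputation
#' settings and analysis options consumed by [run_study()].
#'
#' @param cohort a [cohort_config()].
#' @param effects a [true_effects()] object (projected internally via
#'   [conserved_changes()] for the behavior outcomes).
#' @param imputation an [imputation_spec()].
#' @param outcomes character vector of outcomes to analyze; any of
#'   `"sb"`, `"lpa"`, `"mvpa"`, `"prolonged_sb_min"`, `"prolonged_sb_count"`,
#'   `"bouted_pa_min"`, `"bouted_pa_count"`, `"steps"`, `"k6"`, `"uwes"`,
#'   `"hpq"`.
#' @param seed global seed; stage sub-seeds are derived from it.
#' @param complete_case also run the complete-case sensitivity analysis.
#' @param variance `"stacked"` propagates propensity-score estimation
#'   uncertainty through the sandwich variance; `"fixed"` treats the weights
#'   as known.
#' @param pa_long_runs how bout detection treats PA runs longer than 10
#'   minutes (see [compute_bouts()]).
#' @return object of class `study_config`.
#' @export
study_config <- function(cohort = cohort_config(),
                         effects = true_effects(),
                         imputation = imputation_spec(),
                         outcomes = c("sb", "lpa", "mvpa", "prolonged_sb_min",
                                      "prolonged_sb_count", "bouted_pa_min",
                                      "bouted_pa_count", "steps",
                                      "k6", "uwes", "hpq"),
                         seed = 1L,
                         complete_case = TRUE,
                         variance = c("stacked", "fixed"),
                         pa_long_runs = c("exclude", "truncate")) {
  stopifnot(inherits(cohort, "cohort_config"),
            inherits(effects, "true_effects"),
            inherits(imputation, "imputation_spec"))
  if (length(outcomes) == 0) stop("outcome list is empty", call. = FALSE)
  structure(list(cohort = cohort, effects = effects, imputation = imputation,
                 outcomes = outcomes, seed = as.integer(seed),
                 complete_case = complete_case,
                 variance = match.arg(variance),
                 pa_long_runs = match.arg(pa_long_runs)),
            class = "study_config")
}

# "HH:MM" window -> minutes of day, half-open [start, end)
parse_window <- function(work_window) {
  stopifnot(length(work_window) == 2L)
  mins <- vapply(strsplit(work_window, ":"), function(p) {
    as.integer(p[1]) * 60L + as.integer(p[2])
  }, integer(1))
  if (any(is.na(mins)) || mins[2] <= mins[1])
    stop("work window must be 'HH:MM' times with end after start",
         call. = FALSE)
  mins
}

# deterministic sub-seed derivation, kept within 32-bit range
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 7919 + stream * 104729) %% 2147483587 + 1
}
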