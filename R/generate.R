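#' Generate subject covariates with confounded group assignment
#'
#' Draws one row per subject with age, sex (1 = female), BMI and job
#' position (1 = manager), with exact arm sizes. Per-arm marginal
#' distributions reproduce the study's baseline table at `confounding = 1`
#' (controls older, more male, higher BMI, more managerial); at
#' `confounding = 0` both arms are drawn from the pooled population, so the
#' assignment is unconfounded.
#'
#' @param config a [cohort_config()].
#' @param seed optional integer; defaults to `config$seed`.
#' @return data.frame with columns `id`, `group` (factor
#'   intervention/control), `age`, `sex`, `bmi`, `manager`.
#' @export
#' @examples
#' head(generate_covariates(cohort_config(n_intervention = 5, n_control = 5)))
generate_covariates <- function(config, seed = config$seed) {
  if (config$n_intervention < 1 || config$n_control < 1)
    stop("non-positive arm size", call. = FALSE)
  set.seed(seed)
  cv <- config$covariates
  n <- c(intervention = config$n_intervention, control = config$n_control)
  w <- n / sum(n)
  lambda <- config$confounding

  # pooled population parameters; arm parameters interpolate pooled -> arm
  mix_mean <- function(per_arm) {
    pooled <- w[["intervention"]] * per_arm$intervention[1] +
      w[["control"]] * per_arm$control[1]
    lapply(per_arm, function(x) {
      c(pooled + lambda * (x[1] - pooled), x[2])
    })
  }
  mix_prob <- function(p) {
    pooled <- sum(w * p[c("intervention", "control")])
    # interpolate on the log-odds scale so probabilities stay in (0, 1)
    plogis(qlogis(pooled) + lambda * (qlogis(p) - qlogis(pooled)))
  }

  age <- mix_mean(cv$age)
  bmi <- mix_mean(cv$bmi)
  pf <- mix_prob(cv$p_female)
  pm <- mix_prob(cv$p_manager)

  draw_arm <- function(arm) {
    ni <- n[[arm]]
    data.frame(
      group = arm,
      age = rnorm(ni, age[[arm]][1], age[[arm]][2]),
      sex = rbinom(ni, 1, pf[[arm]]),
      bmi = rnorm(ni, bmi[[arm]][1], bmi[[arm]][2]),
      manager = rbinom(ni, 1, pm[[arm]])
    )
  }
  out <- rbind(draw_arm("intervention"), draw_arm("control"))
  out$age <- pmax(out$age, 18)
  out$bmi <- pmax(out$bmi, 14)
  out$group <- factor(out$group, levels = c("intervention", "control"))
  data.frame(id = seq_len(nrow(out)), out)
}

# draw n sum-zero Gaussian triples with target marginal SDs sds = c(s1,s2,s3);
# the constraint fixes cov(2,3) = (s1^2 - s2^2 - s3^2)/2
rnorm_sumzero <- function(n, sds) {
  s23 <- (sds[1]^2 - sds[2]^2 - sds[3]^2) / 2
  s23 <- max(min(s23, 0.99 * sds[2] * sds[3]), -0.99 * sds[2] * sds[3])
  slope <- if (sds[2] > 0) s23 / sds[2]^2 else 0
  z2 <- rnorm(n, 0, sds[2])
  resid_sd <- sqrt(max(sds[3]^2 - slope^2 * sds[2]^2, 0))
  z3 <- slope * z2 + rnorm(n, 0, resid_sd)
  cbind(-(z2 + z3), z2, z3)
}

# floor components at `lo` while conserving the row sum (deficit taken from
# the largest component)
floor_conserve <- function(m, lo = 0) {
  below <- m < lo
  if (any(below)) {
    deficit <- rowSums((lo - m) * below)
    m[below] <- lo
    top <- max.col(m)
    m[cbind(seq_len(nrow(m)), top)] <-
      m[cbind(seq_len(nrow(m)), top)] - deficit
  }
  m
}

# Subject-level latent behavior profiles and wear-day counts for both
# visits. Baseline standardized-minute triples are arm mean occupancies
# (x 480) plus sum-zero subject deviations; follow-up adds the
# time-conserving projected arm effect plus sum-zero change noise, so every
# latent triple sums to exactly 480 min/8 h.
generate_profiles <- function(subjects, config, effects = true_effects(),
                              seed = config$seed) {
  set.seed(seed)
  eff <- conserved_changes(effects)
  beh <- c("sb", "lpa", "mvpa")
  n <- nrow(subjects)
  truth <- data.frame(id = subjects$id, group = subjects$group)

  base <- matrix(NA_real_, n, 3, dimnames = list(NULL, beh))
  fu <- base
  for (arm in c("intervention", "control")) {
    idx <- which(subjects$group == arm)
    b <- config$behavior[[arm]]
    arm_base <- 480 * b$profile / sum(b$profile)
    dev <- rnorm_sumzero(length(idx), b$sd[beh])
    base[idx, ] <- floor_conserve(
      matrix(arm_base, length(idx), 3, byrow = TRUE) + dev)
    ch <- rnorm_sumzero(length(idx), config$behavior_change_sd[beh])
    delta <- eff[[arm]][beh]
    fu[idx, ] <- floor_conserve(
      base[idx, ] + matrix(delta, length(idx), 3, byrow = TRUE) + ch)
  }
  colnames(base) <- paste0(beh, "_b")
  colnames(fu) <- paste0(beh, "_f")
  truth <- cbind(truth, base, fu)

  for (v in c("b", "f")) {
    truth[[paste0("days_", v)]] <- unsplit(lapply(
      split(seq_len(n), subjects$group), function(idx) {
        arm <- as.character(subjects$group[idx[1]])
        wd <- config$wear_days[[arm]]
        pmax(config$min_days, as.integer(round(rnorm(length(idx), wd[1], wd[2]))))
      }), subjects$group)
  }
  truth
}

# expected MET mass per wear epoch for an occupancy triple (used to
# calibrate the Poisson step rate): SB epochs carry no steps
met_mass <- function(pi, mvpa_excess) {
  pi[2] * 2.25 + pi[3] * (3 + mvpa_excess)
}

# per arm/visit Poisson step rate per MET so that the expected standardized
# step count matches the calibration target
step_rate <- function(config, effects, arm, visit) {
  eff <- conserved_changes(effects)
  b <- config$behavior[[arm]]
  pi <- b$profile / sum(b$profile)
  target <- config$steps_baseline[[arm]]
  if (visit == "followup") {
    pi <- pi + eff[[arm]][c("sb", "lpa", "mvpa")] / 480
    target <- target + effects[[arm]][["steps"]]
  }
  target / (480 * met_mass(unname(pi), config$mvpa_excess))
}

# Vectorized epoch-stream simulation for a set of truth rows (one visit).
# Returns a data.table in the epoch CSV layout: worker_id, date, time, met,
# steps; one row per 60-s epoch of the work window, per wear day.
sim_epochs <- function(truth, config, visit = c("baseline", "followup"),
                       effects = true_effects()) {
  visit <- match.arg(visit)
  win <- config$window_min
  n_steps <- win[2] - win[1]
  sfx <- if (visit == "baseline") "_b" else "_f"
  days <- truth[[paste0("days", sfx)]]
  nd <- sum(days)
  day_subj <- rep(seq_len(nrow(truth)), days)
  day_no <- sequence(days)

  pi_subj <- as.matrix(truth[, paste0(c("sb", "lpa", "mvpa"), sfx)]) / 480
  pi_day <- pi_subj[day_subj, , drop = FALSE]

  arm <- as.character(truth$group)
  mixing_arm <- vapply(c("intervention", "control"), function(a) {
    b <- config$behavior[[a]]
    pi_sb <- b$profile[["sb"]] / sum(b$profile)
    if (pi_sb >= 1) 1 else min(1, (1 - b$sb_persist) / (1 - pi_sb))
  }, numeric(1))
  mixing_day <- mixing_arm[arm][day_subj]

  states <- sim_markov_days(pi_day, mixing_day, n_steps)

  # contiguous device-off block (>= 60 min so the detector can flag it)
  p_block <- config$nonwear_block$prob[arm][day_subj]
  has_block <- runif(nd) < p_block
  if (any(has_block)) {
    len_rng <- config$nonwear_block$length
    bl <- sample(seq(len_rng[1], len_rng[2]), sum(has_block), replace = TRUE)
    bl <- pmin(bl, n_steps)
    st <- floor(runif(sum(has_block)) * (n_steps - bl + 1)) + 1L
    rows <- which(has_block)
    for (j in seq_along(rows))
      states[rows[j], st[j]:(st[j] + bl[j] - 1L)] <- 0L
  }

  s <- as.vector(t(states))  # epoch-major within day
  n_ep <- length(s)
  met <- numeric(n_ep)
  met[s == 1L] <- sample(seq(0.9, 1.5, by = 0.1), sum(s == 1L), replace = TRUE)
  met[s == 2L] <- sample(seq(1.6, 2.9, by = 0.1), sum(s == 2L), replace = TRUE)
  if (any(s == 3L))
    met[s == 3L] <- round(3 + rexp(sum(s == 3L), 1 / config$mvpa_excess), 1)

  rate <- c(intervention = step_rate(config, effects, "intervention", visit),
            control = step_rate(config, effects, "control", visit))
  rate_ep <- rate[arm][rep(day_subj, each = n_steps)]
  steps <- integer(n_ep)
  pa <- s >= 2L
  if (any(pa)) steps[pa] <- rpois(sum(pa), rate_ep[pa] * met[pa])

  t0 <- if (visit == "baseline") as.Date("2019-01-07") else as.Date("2020-02-03")
  times <- sprintf("%02d:%02d:00", (win[1] + 0:(n_steps - 1)) %/% 60,
                   (win[1] + 0:(n_steps - 1)) %% 60)
  data.table::data.table(
    worker_id = rep(truth$id[day_subj], each = n_steps),
    date = t0 + rep(day_no - 1L, each = n_steps),
    time = rep(times, nd),
    met = met,
    steps = steps
  )
}

#' Generate an epoch stream for one subject
#'
#' Emits one 60-s epoch record per work-window minute per wear day for a
#' single subject, following the cohort's wear-state Markov model: MET is 0
#' during device-off blocks, uniform on `[0.9, 1.5]` for sedentary epochs,
#' uniform on `[1.6, 2.9]` for light activity and `3.0 +` exponential for
#' MVPA; steps are Poisson and intensity-proportional during activity
#' epochs and 0 otherwise.
#'
#' @param subject one row of the truth table produced by
#'   [simulate_cohort()] (`$truth`), carrying the subject's latent
#'   standardized-minute profile and wear-day counts.
#' @param config a [cohort_config()].
#' @param visit `"baseline"` or `"followup"`.
#' @param effects a [true_effects()] object (for the step-rate calibration).
#' @param seed integer seed.
#' @return data.table with columns `worker_id`, `date`, `time`, `met`,
#'   `steps`.
#' @export
generate_epoch_stream <- function(subject, config,
                                  visit = c("baseline", "followup"),
                                  effects = true_effects(), seed = 1L) {
  visit <- match.arg(visit)
  if (nrow(subject) != 1L) stop("`subject` must be a single row", call. = FALSE)
  if (!all(c("sb_b", "days_b") %in% names(subject)))
    stop("`subject` must be a truth-table row (see simulate_cohort()$truth)",
         call. = FALSE)
  set.seed(seed)
  sim_epochs(subject, config, visit, effects)
}

# gamma parameterized by mean/sd
qgamma_ms <- function(p, mean, sd) {
  shape <- (mean / sd)^2
  stats::qgamma(p, shape = shape, rate = shape / mean)
}

#' Generate questionnaire outcomes at both visits
#'
#' Latent baseline scale scores are drawn per arm — gamma for psychological
#' distress (right-skewed, non-negative), normal for engagement and
#' presenteeism — and the follow-up latent adds the programmed arm effect
#' plus an independent individual change whose SD is derived from the
#' configured follow-up SD (`change_sd = sqrt(fu_sd^2 - sd^2)`, floored at
#' 0.3). Making the individual change independent of the baseline keeps the
#' within-arm mean change equal to the programmed effect under any
#' baseline-dependent weighting. Latent scores falling outside the
#' instrument range are clamped (a warning reports the count) and
#' decomposed into integer item responses whose standard scoring reproduces
#' the (discretized) score.
#'
#' @param subjects covariate table from [generate_covariates()].
#' @param effects a [true_effects()] object.
#' @param config a [cohort_config()].
#' @param seed integer seed.
#' @return `subjects` with item columns appended: `k6_b_1..6`, `k6_f_1..6`,
#'   `uwes_b_1..9`, `uwes_f_1..9`, `hpq_b`, `hpq_f` (item counts follow the
#'   configuration). Attribute `"clamped"` counts out-of-range latents.
#' @export
generate_outcomes <- function(subjects, effects = true_effects(), config,
                              seed = config$seed) {
  set.seed(seed)
  n <- nrow(subjects)
  clamped <- 0L
  for (inst in c("k6", "uwes", "hpq")) {
    q <- config$questionnaires[[inst]]
    base_lat <- numeric(n)
    fu_lat <- numeric(n)
    for (arm in c("intervention", "control")) {
      idx <- which(subjects$group == arm)
      pars <- q[[arm]]
      m1 <- pars[["mean"]]; s1 <- pars[["sd"]]
      delta <- effects[[arm]][[inst]]
      if (s1 <= 0) {                      # degenerate: no between-subject noise
        base_lat[idx] <- m1; fu_lat[idx] <- m1 + delta; next
      }
      sc <- sqrt(max(pars[["fu_sd"]]^2 - s1^2, 0))
      if (q$family == "gamma") {
        base_lat[idx] <- rgamma(length(idx), shape = (m1 / s1)^2,
                                rate = m1 / s1^2)
        # follow-up conditionally gamma: support stays non-negative and the
        # conditional mean change equals the programmed effect at every
        # baseline, so baseline-dependent weighting cannot bias it
        mu <- pmax(base_lat[idx] + delta, 0.05)
        if (sc > 0) {
          fu_lat[idx] <- rgamma(length(idx), shape = (mu / sc)^2,
                                rate = mu / sc^2)
        } else {
          fu_lat[idx] <- mu
        }
      } else {
        base_lat[idx] <- rnorm(length(idx), m1, s1)
        fu_lat[idx] <- base_lat[idx] + delta +
          if (sc > 0) rnorm(length(idx), 0, sc) else 0
      }
    }
    for (v in c("b", "f")) {
      lat <- if (v == "b") base_lat else fu_lat
      rng <- q$range
      clamped <- clamped + sum(lat < rng[1] | lat > rng[2])
      lat <- pmin(pmax(lat, rng[1]), rng[2])
      if (inst == "uwes") {
        total <- as.integer(round(lat * q$items))   # mean scale -> item total
      } else {
        total <- as.integer(round(lat))
      }
      items <- decompose_score(total, q$items, q$item_max)
      if (q$items == 1L) {
        subjects[[paste0(inst, "_", v)]] <- as.integer(items)
      } else {
        colnames(items) <- paste0(inst, "_", v, "_", seq_len(q$items))
        subjects <- cbind(subjects, as.data.frame(items))
      }
    }
  }
  if (clamped > 0)
    warning(clamped, " latent score(s) clamped to the instrument range",
            call. = FALSE)
  attr(subjects, "clamped") <- clamped
  subjects
}

# integer total -> n_items integers in [0, item_max] summing to the total
decompose_score <- function(total, n_items, item_max) {
  if (any(total < 0 | total > n_items * item_max))
    stop("score outside the representable range", call. = FALSE)
  base <- total %/% n_items
  rem <- total %% n_items
  m <- matrix(base, nrow = length(total), ncol = n_items)
  add <- outer(rem, seq_len(n_items), ">=")
  m + add
}

#' Generate adherence recall responses (intervention arm)
#'
#' Four-level ordinal responses ("almost never" < "sometimes" < "mostly" <
#' "almost always") at three recall points for intervention-arm subjects.
#' The top-category probabilities default to 62.1%, 58.6% and 66.9% at the
#' three points; the remainder is split over the lower categories by the
#' configured proportions.
#'
#' @param subjects covariate table.
#' @param config a [cohort_config()].
#' @param seed integer seed.
#' @return `subjects` with integer columns `adh_1`, `adh_2`, `adh_3`
#'   (1 = almost never ... 4 = almost always; `NA` for control subjects).
#' @export
generate_adherence <- function(subjects, config, seed = config$seed) {
  idx <- which(subjects$group == "intervention")
  if (length(idx) == 0) stop("intervention arm is empty", call. = FALSE)
  set.seed(seed)
  for (t in 1:3) {
    p_aa <- config$adherence$p_always[t]
    probs <- c(config$adherence$rest_split * (1 - p_aa), p_aa)
    if (abs(sum(probs) - 1) > 1e-8 || any(probs < 0))
      stop("adherence probabilities must sum to 1", call. = FALSE)
    col <- rep(NA_integer_, nrow(subjects))
    r <- runif(length(idx))
    col[idx] <- 1L + findInterval(r, cumsum(probs)[1:3])
    subjects[[paste0("adh_", t)]] <- col
  }
  subjects
}

#' Apply missing-at-random missingness and attrition
#'
#' Deletes entries from the generated tables according to per-variable,
#' per-arm rates. Missingness probability follows a logistic model in
#' (standardized) age and sex — higher for younger and female workers by
#' default — with the intercept solved so the arm-level expected rate
#' matches the configured rate; age and sex themselves use
#' rate-only (MCAR) deletion. Accelerometer missingness removes the whole
#' subject-visit epoch stream (the device-level failure mode);
#' questionnaire missingness blanks all items of the instrument at that
#' visit; attrition removes all follow-up records.
#'
#' @param cohort a `deskbreaks_cohort` list from [simulate_cohort()]
#'   (pre-missingness), or any list with compatible elements.
#' @param config a [cohort_config()].
#' @param seed integer seed.
#' @return the cohort with missing entries, plus a `missing_log` data.frame
#'   of realized per-variable missing counts by arm.
#' @export
apply_missingness <- function(cohort, config, seed = config$seed) {
  set.seed(seed)
  subjects <- cohort$subjects
  n <- nrow(subjects)
  arm <- as.character(subjects$group)
  z_age <- as.numeric(scale(subjects$age))
  lin <- 0.4 * -z_age + 0.3 * subjects$sex   # younger, female -> more missing

  draw_miss <- function(rates, mar = TRUE) {
    p <- numeric(n)
    for (a in c("intervention", "control")) {
      idx <- which(arm == a)
      r <- rates[[a]]
      if (r <= 0) { p[idx] <- 0; next }
      if (r >= 1) { p[idx] <- 1; next }
      if (!mar) { p[idx] <- r; next }
      f <- function(a0) mean(plogis(a0 + lin[idx])) - r
      a0 <- uniroot(f, c(-20, 20))$root
      p[idx] <- plogis(a0 + lin[idx])
    }
    runif(n) < p
  }

  log <- list()
  note <- function(var, ind) {
    log[[length(log) + 1]] <<- data.frame(
      variable = var,
      intervention = sum(ind[arm == "intervention"]),
      control = sum(ind[arm == "control"]))
  }

  ms <- config$missingness
  for (v in c("age", "sex")) {
    ind <- draw_miss(ms[[v]], mar = FALSE)
    subjects[[v]][ind] <- NA
    note(v, ind)
  }
  for (v in c("bmi", "manager")) {
    ind <- draw_miss(ms[[v]])
    subjects[[v]][ind] <- NA
    note(v, ind)
  }

  # accelerometer: whole subject-visit stream
  for (v in c("b", "f")) {
    ind <- draw_miss(ms$accel)
    note(paste0("accel_", v), ind)
    drop_ids <- subjects$id[ind]
    el <- paste0("epochs_", if (v == "b") "baseline" else "followup")
    if (!is.null(cohort[[el]]))
      cohort[[el]] <- cohort[[el]][!worker_id %in% drop_ids]
    if (!is.null(cohort$behavior)) {
      vis <- if (v == "b") "baseline" else "followup"
      bcols <- setdiff(names(cohort$behavior), c("id", "visit"))
      cohort$behavior[cohort$behavior$id %in% drop_ids &
                        cohort$behavior$visit == vis, bcols] <- NA
    }
  }

  inst_cols <- function(inst, v) {
    q <- config$questionnaires[[inst]]
    if (q$items == 1L) paste0(inst, "_", v)
    else paste0(inst, "_", v, "_", seq_len(q$items))
  }
  for (inst in c("k6", "uwes", "hpq")) {
    for (v in c("b", "f")) {
      ind <- draw_miss(ms[[inst]])
      subjects[ind, inst_cols(inst, v)] <- NA
      note(paste0(inst, "_", v), ind)
    }
  }

  if (all(c("adh_1", "adh_2", "adh_3") %in% names(subjects))) {
    r <- ms$adherence
    for (t in 1:3) {
      ind <- arm == "intervention" & runif(n) < r
      subjects[[paste0("adh_", t)]][ind] <- NA
      note(paste0("adh_", t), ind)
    }
  }

  # attrition: whole follow-up record
  attr_ind <- draw_miss(ms$attrition)
  if (any(attr_ind)) {
    drop_ids <- subjects$id[attr_ind]
    if (!is.null(cohort$epochs_followup))
      cohort$epochs_followup <- cohort$epochs_followup[!worker_id %in% drop_ids]
    fu_cols <- grep("_f(_|$)", names(subjects), value = TRUE)
    subjects[attr_ind, fu_cols] <- NA
    if (!is.null(cohort$behavior)) {
      bcols <- setdiff(names(cohort$behavior), c("id", "visit"))
      cohort$behavior[cohort$behavior$id %in% drop_ids &
                        cohort$behavior$visit == "followup", bcols] <- NA
    }
  }
  note("attrition", attr_ind)

  cohort$subjects <- subjects
  cohort$missing_log <- do.call(rbind, log)
  cohort
}

# tabular-mode behavior summaries: latent profile + day-averaged
# measurement noise, no epoch data. Mirrors the output layout of
# summarize_subjects().
sim_behavior_tabular <- function(truth, config) {
  # day-to-day SD of standardized metrics, matched to the epoch model
  day_sd <- c(sb = 23, lpa = 22, mvpa = 10.5)
  out <- list()
  for (v in c("b", "f")) {
    visit <- if (v == "b") "baseline" else "followup"
    days <- truth[[paste0("days_", v)]]
    noise <- rnorm_sumzero(nrow(truth), day_sd) / sqrt(days)
    prof <- as.matrix(truth[, paste0(c("sb", "lpa", "mvpa"), "_", v)]) + noise
    rate <- vapply(as.character(truth$group), function(a)
      step_rate(config, true_effects(), a, visit), numeric(1))
    # steps scale with the subject's activity MET mass
    pi <- prof / 480
    steps <- 480 * rate * (pi[, 2] * 2.25 + pi[, 3] * (3 + config$mvpa_excess))
    steps <- steps + rnorm(nrow(truth), 0, 1300 / sqrt(days))
    out[[v]] <- data.frame(
      id = truth$id, visit = visit,
      n_valid_days = days, meets_inclusion = TRUE,
      wear_min = 480, sb = prof[, 1], lpa = prof[, 2], mvpa = prof[, 3],
      prolonged_sb_min = NA_real_, prolonged_sb_count = NA_real_,
      bouted_pa_min = NA_real_, bouted_pa_count = NA_real_,
      steps = pmax(steps, 0))
  }
  rbind(out$b, out$f)
}

#' Simulate a complete synthetic study cohort
#'
#' Runs the full generator: covariates with confounded assignment, latent
#' behavior profiles, epoch streams at both visits (or tabular behavior
#' summaries in `epoch_mode = "tabular"`), questionnaire items, adherence
#' recall, and missing-at-random deletion. Deterministic given
#' `seed`.
#'
#' @param config a [cohort_config()].
#' @param effects a [true_effects()] object; behavior changes are projected
#'   with [conserved_changes()] before being applied.
#' @param seed integer seed (default `config$seed`).
#' @return a list of class `deskbreaks_cohort`: `subjects` (covariates,
#'   item responses, adherence), `truth` (latent per-subject profiles and
#'   wear-day counts), `epochs_baseline`/`epochs_followup` (epoch
#'   data.tables; `NULL` in tabular mode), `behavior` (tabular mode only),
#'   `missing_log`, `config`, `effects_realized`.
#' @export
#' @examples
#' cfg <- cohort_config(n_intervention = 6, n_control = 8, seed = 3)
#' coh <- simulate_cohort(cfg)
#' names(coh)
simulate_cohort <- function(config = cohort_config(),
                            effects = true_effects(),
                            seed = config$seed) {
  subjects <- generate_covariates(config, seed = derive_seed(seed, 1))
  truth <- generate_profiles(subjects, config, effects,
                             seed = derive_seed(seed, 2))
  cohort <- list(subjects = subjects, truth = truth, config = config,
                 effects_realized = conserved_changes(effects))
  if (config$epoch_mode == "markov") {
    set.seed(derive_seed(seed, 3))
    cohort$epochs_baseline <- sim_epochs(truth, config, "baseline", effects)
    set.seed(derive_seed(seed, 4))
    cohort$epochs_followup <- sim_epochs(truth, config, "followup", effects)
  } else {
    set.seed(derive_seed(seed, 3))
    cohort$behavior <- sim_behavior_tabular(truth, config)
  }
  cohort$subjects <- generate_outcomes(cohort$subjects, effects, config,
                                       seed = derive_seed(seed, 5))
  cohort$subjects <- generate_adherence(cohort$subjects, config,
                                        seed = derive_seed(seed, 6))
  cohort <- apply_missingness(cohort, config, seed = derive_seed(seed, 7))
  class(cohort) <- "deskbreaks_cohort"
  cohort
}
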