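ACCEL_OUTCOMES <- c("sb", "lpa", "mvpa", "prolonged_sb_min",
                    "prolonged_sb_count", "bouted_pa_min", "bouted_pa_count",
                    "steps")
SCALE_OUTCOMES <- c("k6", "uwes", "hpq")

# one row per subject: z, covariates, <outcome>_b (baseline) and
# <outcome>_ch (follow-up minus baseline) columns — the change score is the
# analysis variable
build_analysis_table <- function(subjects, behavior_b, behavior_f, config,
                                 outcomes) {
  tbl <- data.frame(id = subjects$id,
                    z = as.numeric(subjects$group == "intervention"),
                    age = subjects$age, sex = subjects$sex,
                    bmi = subjects$bmi, manager = subjects$manager)
  accel <- intersect(outcomes, ACCEL_OUTCOMES)
  get_visit <- function(beh, o) {
    m <- merge(tbl["id"], beh[, c("id", o)], by = "id",
               all.x = TRUE, sort = FALSE)
    m[[o]][match(tbl$id, m$id)]
  }
  for (o in accel) {
    b <- get_visit(behavior_b, o)
    f <- get_visit(behavior_f, o)
    tbl[[paste0(o, "_b")]] <- b
    tbl[[paste0(o, "_ch")]] <- f - b
  }
  scored <- score_questionnaires(subjects, config)
  for (o in intersect(outcomes, SCALE_OUTCOMES)) {
    tbl[[paste0(o, "_b")]] <- scored[[paste0(o, "_b_score")]]
    tbl[[paste0(o, "_ch")]] <- scored[[paste0(o, "_f_score")]] -
      scored[[paste0(o, "_b_score")]]
  }
  tbl
}

# Impute the analysis table. Standardized SB/LPA/MVPA satisfy exact linear
# identities (baselines sum to 480, changes to 0); feeding a complete
# dependent set to the chained equations makes jointly missing triples
# self-referential, so MVPA columns are removed before imputation and
# reconstructed from the identities afterwards.
impute_analysis_table <- function(tbl, spec, outcomes) {
  beh <- c("sb", "lpa", "mvpa")
  derive_mvpa <- all(beh %in% outcomes)
  cols <- names(tbl)
  if (derive_mvpa)
    cols <- setdiff(cols, c("mvpa_b", "mvpa_ch"))
  imputed <- impute_pmm(tbl[cols], spec, exclude = "id")
  if (derive_mvpa) {
    imputed <- lapply(imputed, function(d) {
      d$mvpa_b <- 480 - d$sb_b - d$lpa_b
      d$mvpa_ch <- -(d$sb_ch + d$lpa_ch)
      d
    })
  }
  imputed
}

# ATO analysis of one outcome on one completed dataset
analyze_outcome_once <- function(data, outcome, variance = "stacked") {
  base_col <- paste0(outcome, "_b")
  y <- data[[paste0(outcome, "_ch")]]
  covs <- c("age", "sex", "bmi", "manager", base_col)
  ps <- fit_ps_logistic(data, "z", covs)
  inf <- ato_inference(ps, y, variance = variance)
  list(inference = inf, ps = ps, covariates = covs)
}

# pooled MI analysis of one outcome across completed datasets
analyze_outcome_mi <- function(imputed, outcome, variance = "stacked") {
  fits <- lapply(imputed, analyze_outcome_once, outcome = outcome,
                 variance = variance)
  pull <- function(f) f$inference
  tau <- pool_rubin(vapply(fits, function(f) pull(f)$tau, numeric(1)),
                    vapply(fits, function(f) pull(f)$se_tau^2, numeric(1)))
  mu1 <- pool_rubin(vapply(fits, function(f) pull(f)$mu1, numeric(1)),
                    vapply(fits, function(f) pull(f)$se_mu1^2, numeric(1)))
  mu0 <- pool_rubin(vapply(fits, function(f) pull(f)$mu0, numeric(1)),
                    vapply(fits, function(f) pull(f)$se_mu0^2, numeric(1)))
  list(tau = tau, mu1 = mu1, mu0 = mu0, first_fit = fits[[1]])
}

#' Baseline characteristics table
#'
#' Per-variable arm summaries — mean (SD) for continuous variables, n (%)
#' for binary ones — with missing counts and a two-group test p-value:
#' Welch's unequal-variance t-test for continuous variables, Pearson's
#' chi-square for binary ones. A variable observed in only one arm gets no
#' p-value.
#'
#' @param data data.frame containing `group` (intervention/control) and the
#'   variables to summarize.
#' @param variables named character vector: names are column names, values
#'   `"continuous"` or `"binary"`.
#' @return data.frame with one row per variable.
#' @export
baseline_table <- function(data, variables) {
  g1 <- data$group == "intervention"
  rows <- lapply(names(variables), function(v) {
    x <- data[[v]]
    type <- variables[[v]]
    x1 <- x[g1]; x0 <- x[!g1]
    n1 <- sum(!is.na(x1)); n0 <- sum(!is.na(x0))
    p <- NA_real_
    note <- ""
    if (n1 == 0 || n0 == 0) {
      note <- "observed in one arm only"
    } else if (type == "continuous") {
      p <- tryCatch(t.test(x1, x0)$p.value, error = function(e) NA_real_)
    } else {
      tab <- table(factor(x[!is.na(x)], levels = 0:1),
                   factor(data$group[!is.na(x)]))
      p <- tryCatch(suppressWarnings(chisq.test(tab)$p.value),
                    error = function(e) NA_real_)
    }
    if (type == "continuous") {
      data.frame(variable = v, type = type,
                 intervention = sprintf("%.1f (%.1f)", mean(x1, na.rm = TRUE),
                                        sd(x1, na.rm = TRUE)),
                 control = sprintf("%.1f (%.1f)", mean(x0, na.rm = TRUE),
                                   sd(x0, na.rm = TRUE)),
                 missing_intervention = sum(is.na(x1)),
                 missing_control = sum(is.na(x0)), p_value = p, note = note)
    } else {
      data.frame(variable = v, type = type,
                 intervention = sprintf("%d (%.1f%%)", sum(x1 == 1, na.rm = TRUE),
                                        100 * mean(x1 == 1, na.rm = TRUE)),
                 control = sprintf("%d (%.1f%%)", sum(x0 == 1, na.rm = TRUE),
                                   100 * mean(x0 == 1, na.rm = TRUE)),
                 missing_intervention = sum(is.na(x1)),
                 missing_control = sum(is.na(x0)), p_value = p, note = note)
    }
  })
  do.call(rbind, rows)
}

# observed-only pre/post mean (SD) per arm for the results table
describe_prepost <- function(tbl, outcome) {
  out <- list()
  for (arm in c(1, 0)) {
    sel <- tbl$z == arm
    b <- tbl[[paste0(outcome, "_b")]][sel]
    f <- b + tbl[[paste0(outcome, "_ch")]][sel]
    out[[paste0(if (arm == 1) "int" else "ctl", "_b")]] <-
      sprintf("%.1f (%.1f)", mean(b, na.rm = TRUE), sd(b, na.rm = TRUE))
    out[[paste0(if (arm == 1) "int" else "ctl", "_f")]] <-
      sprintf("%.1f (%.1f)", mean(f, na.rm = TRUE), sd(f, na.rm = TRUE))
  }
  out
}

#' Run the full synthetic study
#'
#' End-to-end pipeline: simulate the cohort, process epoch streams into
#' occupational behavior metrics, score questionnaires, multiply impute
#' missing data, and estimate overlap-weighted (ATO) within-arm changes and
#' group differences per outcome with Rubin pooling; optionally also the
#' complete-case sensitivity analysis. Deterministic given `config$seed`.
#'
#' @param config a [study_config()].
#' @param minimal when `TRUE`, skip the descriptive tables, balance report
#'   and complete-case analysis (used by simulation studies).
#' @return list of class `study_report`: `results` (one row per outcome:
#'   observed pre/post mean (SD) per arm, pooled within-arm changes with
#'   CIs, ATO group difference with CI and p), `complete_case`, `baseline`,
#'   `adherence`, `balance`, `missing_log`, `analysis_table`, `meta`.
#' @export
#' @examples
#' \donttest{
#' cfg <- study_config(cohort = cohort_config(n_intervention = 40,
#'                                            n_control = 60),
#'                     imputation = imputation_spec(m = 3), seed = 1)
#' rep <- run_study(cfg)
#' rep$results[, c("outcome", "diff", "diff_p")]
#' }
run_study <- function(config = study_config(), minimal = FALSE) {
  stopifnot(inherits(config, "study_config"))
  t_start <- Sys.time()
  cohort <- simulate_cohort(config$cohort, config$effects,
                            seed = config$seed)

  if (config$cohort$epoch_mode == "markov") {
    proc_b <- process_accelerometry(cohort$epochs_baseline,
                                    window = config$cohort$work_window,
                                    pa_long_runs = config$pa_long_runs)
    proc_f <- process_accelerometry(cohort$epochs_followup,
                                    window = config$cohort$work_window,
                                    pa_long_runs = config$pa_long_runs)
    behavior_b <- as.data.frame(proc_b$subjects)
    behavior_f <- as.data.frame(proc_f$subjects)
  } else {
    behavior_b <- cohort$behavior[cohort$behavior$visit == "baseline", ]
    behavior_f <- cohort$behavior[cohort$behavior$visit == "followup", ]
    avail <- names(which(!vapply(behavior_b[ACCEL_OUTCOMES],
                                 function(x) all(is.na(x)), logical(1))))
    drop <- setdiff(intersect(config$outcomes, ACCEL_OUTCOMES), avail)
    if (length(drop) > 0)
      config$outcomes <- setdiff(config$outcomes, drop)
  }

  tbl <- build_analysis_table(cohort$subjects, behavior_b, behavior_f,
                              config$cohort, config$outcomes)

  spec <- config$imputation
  spec$seed <- derive_seed(config$seed, 11)
  imputed <- impute_analysis_table(tbl, spec, config$outcomes)

  results <- list()
  cc_results <- list()
  balance <- list()
  for (o in config$outcomes) {
    mi <- analyze_outcome_mi(imputed, o, variance = config$variance)
    desc <- describe_prepost(tbl, o)
    results[[o]] <- data.frame(
      outcome = o,
      pre_intervention = desc$int_b, post_intervention = desc$int_f,
      pre_control = desc$ctl_b, post_control = desc$ctl_f,
      change_intervention = mi$mu1$estimate,
      change_intervention_lo = mi$mu1$ci[1], change_intervention_hi = mi$mu1$ci[2],
      change_control = mi$mu0$estimate,
      change_control_lo = mi$mu0$ci[1], change_control_hi = mi$mu0$ci[2],
      diff = mi$tau$estimate, diff_lo = mi$tau$ci[1], diff_hi = mi$tau$ci[2],
      diff_p = mi$tau$p)

    if (!minimal) {
      fit <- mi$first_fit
      bal <- balance_diagnostics(imputed[[1]], fit$covariates,
                                 z = imputed[[1]]$z,
                                 w = fit$inference$weights, ps = fit$ps$ps)
      balance[[o]] <- data.frame(outcome = o, bal$smd)
      if (config$complete_case) {
        need <- c("z", "age", "sex", "bmi", "manager",
                  paste0(o, c("_b", "_ch")))
        cc <- tbl[complete.cases(tbl[need]), ]
        if (length(unique(cc$z)) == 2) {
          f <- analyze_outcome_once(cc, o, variance = config$variance)$inference
          cc_results[[o]] <- data.frame(
            outcome = o, n = nrow(cc),
            change_intervention = f$mu1, change_control = f$mu0,
            diff = f$tau, diff_lo = f$ci[1], diff_hi = f$ci[2], diff_p = f$p)
        }
      }
    }
  }

  report <- list(results = do.call(rbind, results),
                 complete_case = if (length(cc_results) > 0)
                   do.call(rbind, cc_results) else NULL,
                 missing_log = cohort$missing_log,
                 analysis_table = tbl,
                 effects_realized = cohort$effects_realized,
                 meta = list(seed = config$seed,
                             n_intervention = config$cohort$n_intervention,
                             n_control = config$cohort$n_control,
                             m = config$imputation$m,
                             epoch_mode = config$cohort$epoch_mode,
                             runtime_s = as.numeric(difftime(Sys.time(),
                                                             t_start,
                                                             units = "secs"))))
  if (!minimal) {
    base_data <- data.frame(group = cohort$subjects$group, tbl)
    vars <- c(age = "continuous", sex = "binary", bmi = "continuous",
              manager = "binary")
    for (o in config$outcomes)
      vars[paste0(o, "_b")] <- "continuous"
    report$baseline <- baseline_table(base_data, vars)
    report$adherence <- summarize_adherence(
      cohort$subjects[cohort$subjects$group == "intervention", ])
    report$balance <- if (length(balance) > 0) do.call(rbind, balance) else NULL
  }
  class(report) <- "study_report"
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("Synthetic workplace active-break study report\n")
  cat(sprintf("  arms: %d intervention / %d control, %d imputations, seed %d\n",
              x$meta$n_intervention, x$meta$n_control, x$meta$m, x$meta$seed))
  cat("\nOverlap-weighted (ATO) results:\n")
  r <- x$results
  for (i in seq_len(nrow(r)))
    cat(sprintf(
      "  %-18s change int %7.2f (%.2f, %.2f)  ctl %6.2f  diff %7.2f (%.2f, %.2f) p=%.3g\n",
      r$outcome[i], r$change_intervention[i], r$change_intervention_lo[i],
      r$change_intervention_hi[i], r$change_control[i], r$diff[i],
      r$diff_lo[i], r$diff_hi[i], r$diff_p[i]))
  invisible(x)
}

#' Replicate the study pipeline for a Monte-Carlo simulation
#'
#' Runs [run_study()] once per seed and collects per-replicate pooled
#' within-arm changes and group differences per outcome, for
#' parameter-recovery and calibration studies.
#'
#' @param config a [study_config()]; its seed is replaced per replicate.
#' @param seeds integer vector of replicate seeds.
#' @param minimal passed to [run_study()] (default `TRUE`).
#' @return data.frame with one row per replicate x outcome: `seed`,
#'   `outcome`, `change_intervention`, `change_control`, `diff`, `diff_lo`,
#'   `diff_hi`, `diff_p`.
#' @export
run_replicates <- function(config, seeds, minimal = TRUE) {
  out <- lapply(seeds, function(s) {
    cfg <- config
    cfg$seed <- as.integer(s)
    rep <- run_study(cfg, minimal = minimal)
    data.frame(seed = s, rep$results[, c("outcome", "change_intervention",
                                         "change_control", "diff",
                                         "diff_lo", "diff_hi", "diff_p")],
               row.names = NULL)
  })
  do.call(rbind, out)
}
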