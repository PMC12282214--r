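test_that("covariate generation gives exact arm sizes and calibrated means", {
  cfg <- cohort_config(n_intervention = 2, n_control = 2)
  cov <- generate_covariates(cfg, seed = 1)
  expect_equal(nrow(cov), 4L)
  expect_equal(as.vector(table(cov$group)), c(2L, 2L))

  # intervention mean age ~ 45.3 within 1 yr averaged over 50 draws
  ages <- vapply(1:50, function(s) {
    cov <- generate_covariates(cohort_config(), seed = s)
    mean(cov$age[cov$group == "intervention"])
  }, numeric(1))
  expect_lt(abs(mean(ages) - 45.3), 1)
})

test_that("zero confounding removes between-arm covariate differences", {
  cfg <- cohort_config(n_intervention = 2000, n_control = 2000,
                       confounding = 0)
  cov <- generate_covariates(cfg, seed = 3)
  i <- cov$group == "intervention"
  expect_lt(abs(mean(cov$age[i]) - mean(cov$age[!i])), 1)
  expect_lt(abs(mean(cov$sex[i]) - mean(cov$sex[!i])), 0.05)
  expect_lt(abs(mean(cov$manager[i]) - mean(cov$manager[!i])), 0.05)
})

test_that("latent profiles conserve the 480-minute workday at both visits", {
  cfg <- small_config(40, 60)
  cov <- generate_covariates(cfg, seed = 2)
  truth <- deskbreaks:::generate_profiles(cov, cfg, true_effects(), seed = 2)
  expect_equal(truth$sb_b + truth$lpa_b + truth$mvpa_b, rep(480, 100),
               tolerance = 1e-9)
  expect_equal(truth$sb_f + truth$lpa_f + truth$mvpa_f, rep(480, 100),
               tolerance = 1e-9)
  expect_true(all(truth[c("sb_b", "lpa_b", "mvpa_b",
                          "sb_f", "lpa_f", "mvpa_f")] >= 0))
})

test_that("epoch streams cover the work window and respect state structure", {
  cfg <- small_config(6, 6)
  coh <- suppressWarnings(simulate_cohort(cfg))
  ep <- coh$epochs_baseline
  # per worker-day: one record per window epoch, conservation by construction
  cnt <- ep[, .N, by = .(worker_id, date)]
  expect_true(all(cnt$N == 480L))
  expect_true(all(ep$met >= 0))
  expect_true(all(ep$steps[ep$met <= 1.5] == 0))   # SB and non-wear: no steps
  # device-off runs are >= 60 epochs
  r <- rle(ep$met == 0)
  expect_true(all(r$lengths[r$values] >= 60))
})

test_that("a pure-sedentary profile yields all-SB classification downstream", {
  cfg <- small_config(3, 3)
  cfg$behavior$intervention$profile <- c(sb = 480, lpa = 0, mvpa = 0)
  cfg$behavior$intervention$sd <- c(sb = 0, lpa = 0, mvpa = 0)
  cfg$behavior$intervention$wear_mean <- 480
  cfg$nonwear_block$prob <- c(intervention = 0, control = 0)
  eff <- true_effects(
    intervention = c(sb = 0, lpa = 0, mvpa = 0, steps = 0, k6 = 0,
                     uwes = 0, hpq = 0),
    control = c(sb = 0, lpa = 0, mvpa = 0, steps = 0, k6 = 0,
                uwes = 0, hpq = 0))
  coh <- suppressWarnings(simulate_cohort(cfg, eff))
  ids <- coh$subjects$id[coh$subjects$group == "intervention"]
  ep <- coh$epochs_baseline[worker_id %in% ids]
  if (nrow(ep) > 0)
    expect_true(all(classify_epoch(ep$met) == "SB"))
})

test_that("cohort simulation is deterministic given the seed", {
  cfg <- small_config(8, 10, seed = 9)
  a <- suppressWarnings(simulate_cohort(cfg))
  b <- suppressWarnings(simulate_cohort(cfg))
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$epochs_baseline, b$epochs_baseline)
  expect_identical(a$epochs_followup, b$epochs_followup)
  expect_identical(a$truth, b$truth)
})

test_that("questionnaire decomposition and scoring are inverse on the score lattice", {
  # K6: every total 0..24 survives decompose -> sum
  totals <- 0:24
  items <- deskbreaks:::decompose_score(totals, 6, 4)
  expect_true(all(items >= 0 & items <= 4))
  expect_equal(unname(rowSums(items)), totals)
  # engagement: every representable mean total 0..54 over 9 items
  totals <- 0:54
  items <- deskbreaks:::decompose_score(totals, 9, 6)
  expect_equal(unname(rowSums(items)), totals)
  expect_error(deskbreaks:::decompose_score(25, 6, 4), "range")
})

test_that("zero effects with zero noise give identical visit scores", {
  cfg <- small_config(5, 5)
  for (inst in c("k6", "uwes", "hpq")) {
    cfg$questionnaires[[inst]]$intervention[c("sd", "fu_sd")] <- 0
    cfg$questionnaires[[inst]]$control[c("sd", "fu_sd")] <- 0
  }
  eff <- true_effects(
    intervention = c(sb = 0, lpa = 0, mvpa = 0, steps = 0, k6 = 0,
                     uwes = 0, hpq = 0),
    control = c(sb = 0, lpa = 0, mvpa = 0, steps = 0, k6 = 0,
                uwes = 0, hpq = 0))
  cov <- generate_covariates(cfg, seed = 4)
  out <- generate_outcomes(cov, eff, cfg, seed = 4)
  scored <- deskbreaks:::score_questionnaires(out, cfg)
  for (inst in c("k6", "uwes", "hpq"))
    expect_equal(scored[[paste0(inst, "_b_score")]],
                 scored[[paste0(inst, "_f_score")]])
})

test_that("programmed questionnaire effects shift mean scores by the effect", {
  cfg <- cohort_config(n_intervention = 4000, n_control = 4000)
  cov <- generate_covariates(cfg, seed = 5)
  out <- generate_outcomes(cov, true_effects(), cfg, seed = 5)
  scored <- deskbreaks:::score_questionnaires(out, cfg)
  ch <- scored$k6_f_score - scored$k6_b_score
  expect_lt(abs(mean(ch[scored$group == "intervention"]) - 1.6), 0.12)
  ch <- scored$uwes_f_score - scored$uwes_b_score
  expect_lt(abs(mean(ch[scored$group == "intervention"]) - (-0.1)), 0.03)
})

test_that("missingness deletion matches configured rates and is MAR", {
  cfg <- cohort_config(n_intervention = 4000, n_control = 4000)
  cfg$missingness$accel <- c(intervention = 0.3, control = 0.3)
  cov <- generate_covariates(cfg, seed = 6)
  truth <- deskbreaks:::generate_profiles(cov, cfg, true_effects(), seed = 6)
  coh <- list(subjects = cov, truth = truth,
              behavior = deskbreaks:::sim_behavior_tabular(truth, cfg))
  coh$subjects <- generate_outcomes(coh$subjects, true_effects(), cfg, seed = 6)
  coh <- apply_missingness(coh, cfg, seed = 6)
  bb <- coh$behavior[coh$behavior$visit == "baseline", ]
  ind <- is.na(bb$sb[match(coh$subjects$id, bb$id)])
  expect_lt(abs(mean(ind) - 0.3), 0.02)
  # logistic refit recovers the programmed MAR coefficients (-0.4 z-age,
  # 0.3 sex); one arm only, because the solved intercept is arm-specific
  arm <- coh$subjects$group == "intervention"
  d <- data.frame(ind = ind[arm],
                  zage = as.numeric(scale(coh$subjects$age))[arm],
                  sex = coh$subjects$sex[arm])
  fit <- glm(ind ~ zage + sex, family = binomial(), data = d)
  se <- summary(fit)$coefficients[, 2]
  expect_lt(abs(coef(fit)[["zage"]] - (-0.4)), 3 * se[["zage"]])
  expect_lt(abs(coef(fit)[["sex"]] - 0.3), 3 * se[["sex"]])
})

test_that("zero missingness rates leave the cohort untouched", {
  cfg <- no_missing(small_config(10, 10, seed = 12))
  coh <- suppressWarnings(simulate_cohort(cfg))
  expect_true(all(!is.na(coh$subjects$age)))
  expect_true(all(!is.na(coh$subjects[, grep("^k6_", names(coh$subjects))])))
  expect_equal(sum(coh$missing_log$intervention) +
                 sum(coh$missing_log$control), 0)
})

test_that("adherence responses follow the configured category probabilities", {
  cfg <- no_missing(cohort_config(n_intervention = 10000, n_control = 2))
  cov <- generate_covariates(cfg, seed = 8)
  adh <- generate_adherence(cov, cfg, seed = 8)
  i <- adh$group == "intervention"
  for (t in 1:3) {
    share <- mean(adh[[paste0("adh_", t)]][i] == 4L)
    expect_lt(abs(share - cfg$adherence$p_always[t]), 0.015)
  }
  # degenerate probabilities give a constant response
  cfg$adherence$p_always <- c(1, 1, 1)
  adh <- generate_adherence(cov, cfg, seed = 8)
  expect_true(all(adh$adh_1[i] == 4L))
  expect_error(generate_adherence(cov[cov$group == "control", ], cfg),
               "intervention arm")
})
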