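sim_logistic <- function(n, beta, seed) {
  set.seed(seed)
  x1 <- rnorm(n)
  x2 <- rbinom(n, 1, 0.5)
  eta <- beta[1] + beta[2] * x1 + beta[3] * x2
  data.frame(z = rbinom(n, 1, plogis(eta)), x1 = x1, x2 = x2)
}

test_that("propensity fitting solves the logistic score equations", {
  d <- sim_logistic(400, c(-0.5, 0.8, -0.6), seed = 1)
  # intercept-only: every propensity equals the prevalence
  f0 <- fit_ps_logistic(d, "z", character(0))
  expect_equal(unname(f0$ps), rep(mean(d$z), 400), tolerance = 1e-9)

  f <- fit_ps_logistic(d, "z", c("x1", "x2"))
  expect_equal(mean(f$ps), mean(d$z), tolerance = 1e-9)  # score identity
  expect_lt(max(abs(crossprod(f$X, d$z - f$ps))), 1e-8)
  expect_true(all(f$ps > 0 & f$ps < 1))

  # coefficient recovery at n = 5000, within 3 SE of the truth
  d5 <- sim_logistic(5000, c(-0.5, 0.8, -0.6), seed = 2)
  f5 <- fit_ps_logistic(d5, "z", c("x1", "x2"))
  g <- glm(z ~ x1 + x2, binomial(), data = d5)
  se <- sqrt(diag(vcov(g)))
  expect_true(all(abs(f5$coefficients - c(-0.5, 0.8, -0.6)) < 3 * se))
  expect_equal(unname(f5$coefficients), unname(coef(g)), tolerance = 1e-6)

  # perfect separation is reported, not silently clipped
  sep <- data.frame(z = rep(0:1, each = 20), x = c(rnorm(20), rnorm(20) + 50))
  expect_error(fit_ps_logistic(sep, "z", "x"), "separation|converge")
})

test_that("overlap weights follow the PS/1-PS rule without trimming", {
  expect_equal(overlap_weights(c(0.5, 0.9, 0.9), z = c(1, 0, 1)),
               c(0.5, 0.9, 0.1))
  e <- c(0.999999, 0.000001)
  expect_equal(overlap_weights(e, z = c(1, 0)), c(1e-6, 1e-6),
               tolerance = 1e-9)
  expect_error(overlap_weights(c(0, 0.5), z = c(1, 0)), "strictly")
})

test_that("the Hajek contrast reproduces hand-computed toys", {
  est <- estimate_ato(y = c(10, 20, 0, 10), z = c(1, 1, 0, 0),
                      w = c(0.25, 0.75, 0.5, 0.5))
  expect_equal(est$mu1, 17.5)
  expect_equal(est$mu0, 5)
  expect_equal(est$tau, 12.5)

  # equal weights: difference of arm means
  y <- c(4, 6, 8, 1, 3)
  z <- c(1, 1, 1, 0, 0)
  est <- estimate_ato(y, z, rep(0.3, 5))
  expect_equal(est$tau, 6 - 2)
  # constant outcome: zero effect
  expect_equal(estimate_ato(rep(7, 5), z, runif(5))$tau, 0)
  expect_error(estimate_ato(y, z, c(0, 0, 0, 1, 1)), "zero total weight")
})

test_that("stacked sandwich reduces to the classical robust SE without covariates", {
  set.seed(13)
  n <- 150
  z <- rbinom(n, 1, 0.45)
  y <- 2 + 1.5 * z + rnorm(n)
  f0 <- fit_ps_logistic(data.frame(z = z), "z", character(0))
  inf <- ato_inference(f0, y, variance = "stacked")
  n1 <- sum(z); n0 <- n - n1
  se_classic <- sqrt(sum((y[z == 1] - mean(y[z == 1]))^2) / n1^2 +
                     sum((y[z == 0] - mean(y[z == 0]))^2) / n0^2)
  expect_equal(inf$tau, mean(y[z == 1]) - mean(y[z == 0]), tolerance = 1e-9)
  expect_equal(inf$se_tau, se_classic, tolerance = 1e-6)

  # scale equivariance: doubling the outcome doubles the SE
  inf2 <- ato_inference(f0, 2 * y, variance = "stacked")
  expect_equal(inf2$se_tau, 2 * inf$se_tau, tolerance = 1e-9)
  # location invariance: adding a constant moves means, not the contrast
  inf3 <- ato_inference(f0, y + 100, variance = "stacked")
  expect_equal(inf3$tau, inf$tau, tolerance = 1e-9)
  expect_equal(inf3$se_tau, inf$se_tau, tolerance = 1e-9)
})

test_that("overlap weighting balances every model covariate exactly", {
  d <- sim_logistic(600, c(-0.3, 0.9, -0.7), seed = 4)
  d$x3 <- rnorm(600, 2, 3)
  f <- fit_ps_logistic(d, "z", c("x1", "x2", "x3"))
  w <- overlap_weights(f)
  bal <- balance_diagnostics(d, c("x1", "x2", "x3"), d$z, w, ps = f$ps)
  expect_true(all(abs(bal$smd$wmean_diff) < 1e-8))
  expect_equal(nrow(bal$ps_summary), 2L)
})

test_that("weighting reduces the confounded age imbalance of the cohort", {
  cov <- generate_covariates(cohort_config(), seed = 21)
  d <- data.frame(z = as.numeric(cov$group == "intervention"),
                  age = cov$age, sex = cov$sex, bmi = cov$bmi,
                  manager = cov$manager)
  f <- fit_ps_logistic(d, "z", c("age", "sex", "bmi", "manager"))
  w <- overlap_weights(f)
  bal <- balance_diagnostics(d, c("age", "sex", "bmi", "manager"), d$z, w)
  age <- bal$smd[bal$smd$covariate == "age", ]
  expect_gt(abs(age$smd_unweighted), abs(age$smd_weighted))
  expect_lt(abs(age$wmean_diff), 1e-8)
})

test_that("stacked and fixed-weight variances differ as documented", {
  d <- sim_logistic(300, c(-0.2, 0.7, -0.5), seed = 6)
  y <- 1 + 0.5 * d$x1 + rnorm(300)
  f <- fit_ps_logistic(d, "z", c("x1", "x2"))
  st <- ato_inference(f, y, variance = "stacked")
  fx <- ato_inference(f, y, variance = "fixed")
  expect_equal(st$tau, fx$tau)          # same point estimate
  expect_false(isTRUE(all.equal(st$se_tau, fx$se_tau)))
  expect_true(st$p >= 0 && st$p <= 1)
  expect_true(st$ci[1] < st$tau && st$tau < st$ci[2])
})
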