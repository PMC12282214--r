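#' Fit the propensity-score logistic model
#'
#' Maximum-likelihood logistic regression of the group indicator on the
#' balancing covariates (age, sex, BMI, job position and the outcome's
#' baseline value, in the study's specification). The fit is obtained by
#' iteratively reweighted least squares and then polished with Newton steps
#' until the score-equation norm `max |X'(z - e)|` falls below `tol`, so
#' the exact-balance identity of overlap weights holds to numerical
#' precision.
#'
#' @param data data.frame with complete covariates.
#' @param treat name of the 0/1 treatment column (1 = intervention), or a
#'   logical/numeric vector.
#' @param covariates character vector of covariate column names.
#' @param tol score-equation tolerance.
#' @param max_iter iteration cap.
#' @return object of class `ps_model`: `coefficients`, `ps` (fitted
#'   probabilities, all in (0,1)), `X` (model matrix), `z` (treatment),
#'   `converged`, `iterations`.
#' @export
#' @examples
#' d <- data.frame(z = rbinom(100, 1, 0.4), x = rnorm(100))
#' fit <- fit_ps_logistic(d, "z", "x")
#' range(fit$ps)
fit_ps_logistic <- function(data, treat, covariates, tol = 1e-8,
                            max_iter = 100L) {
  z <- if (is.character(treat) && length(treat) == 1) data[[treat]] else treat
  z <- as.numeric(z)
  if (!all(z %in% c(0, 1))) stop("treatment must be 0/1", call. = FALSE)
  if (length(unique(z)) < 2) stop("both groups must be present", call. = FALSE)
  X <- cbind(`(Intercept)` = 1, as.matrix(data[covariates]))
  if (any(is.na(X))) stop("missing covariate values", call. = FALSE)

  fit <- suppressWarnings(
    glm.fit(X, z, family = binomial(),
            control = glm.control(epsilon = 1e-12, maxit = max_iter)))
  beta <- fit$coefficients
  e <- drop(plogis(X %*% beta))

  iter <- fit$iter
  score_norm <- max(abs(crossprod(X, z - e)))
  while (score_norm > tol && iter < max_iter) {      # Newton polish
    Winfo <- e * (1 - e)
    H <- crossprod(X * Winfo, X)
    step <- tryCatch(solve(H, crossprod(X, z - e)), error = function(err) NULL)
    if (is.null(step)) break
    beta <- beta + drop(step)
    e <- drop(plogis(X %*% beta))
    score_norm <- max(abs(crossprod(X, z - e)))
    iter <- iter + 1L
  }

  eps <- 1e-10
  if (any(e < eps) || any(e > 1 - eps)) {
    worst <- names(beta)[which.max(abs(beta[-1])) + 1L]
    stop("propensity scores degenerate at 0/1 (possible separation by '",
         worst, "')", call. = FALSE)
  }
  if (score_norm > tol)
    stop("propensity model did not converge after ", iter,
         " iterations (score norm ", signif(score_norm, 3), ")",
         call. = FALSE)

  structure(list(coefficients = beta, ps = e, X = X, z = z,
                 converged = TRUE, iterations = iter),
            class = "ps_model")
}

#' Overlap weights
#'
#' `w = 1 - PS` for intervention subjects and `w = PS` for controls — the
#' weights that target the average treatment effect in the overlap
#' population (ATO). Subjects with extreme propensity scores get small
#' weights; no trimming or truncation is applied.
#'
#' @param ps fitted propensity scores in (0, 1), or a `ps_model`.
#' @param z 0/1 treatment indicator (ignored when `ps` is a `ps_model`).
#' @return numeric weights in (0, 1).
#' @export
#' @examples
#' overlap_weights(c(0.9, 0.9), z = c(1, 0))  # 0.1, 0.9
overlap_weights <- function(ps, z = NULL) {
  if (inherits(ps, "ps_model")) {
    z <- ps$z
    ps <- ps$ps
  }
  if (any(ps <= 0) || any(ps >= 1))
    stop("propensity scores must lie strictly in (0, 1)", call. = FALSE)
  z * (1 - ps) + (1 - z) * ps
}

#' Overlap-weighted within-arm means and ATO contrast
#'
#' Hajek (ratio) estimator: each arm's weighted mean change and their
#' difference, the ATO effect.
#'
#' @param y outcome (change score) vector.
#' @param z 0/1 treatment indicator.
#' @param w overlap weights.
#' @return list with `mu1` (intervention weighted mean), `mu0` (control),
#'   `tau = mu1 - mu0`.
#' @export
#' @examples
#' estimate_ato(y = c(10, 20, 0, 10), z = c(1, 1, 0, 0),
#'              w = c(0.25, 0.75, 0.5, 0.5))  # tau = 12.5
estimate_ato <- function(y, z, w) {
  if (sum(w[z == 1]) <= 0 || sum(w[z == 0]) <= 0)
    stop("an arm has zero total weight", call. = FALSE)
  mu1 <- sum(w * z * y) / sum(w * z)
  mu0 <- sum(w * (1 - z) * y) / sum(w * (1 - z))
  list(mu1 = mu1, mu0 = mu0, tau = mu1 - mu0)
}

#' ATO inference with sandwich variance
#'
#' Estimates the overlap-weighted arm means and their contrast and computes
#' standard errors from the M-estimation sandwich `A^-1 B A^-T` of the
#' stacked estimating equations (logistic score equations plus the two
#' weighted-mean equations), so the uncertainty of the estimated propensity
#' scores propagates into the variance (`variance = "stacked"`, the
#' default). `variance = "fixed"` treats the weights as known.
#' Single-dataset inference uses the normal reference distribution;
#' t-based small-sample inference applies after Rubin pooling.
#'
#' @param ps_model a fitted [fit_ps_logistic()] model.
#' @param y outcome (change score) vector aligned with the model rows.
#' @param variance `"stacked"` or `"fixed"`.
#' @param conf confidence level.
#' @return list of class `ato_estimate`: `mu1`, `mu0`, `tau`, `se_tau`,
#'   `se_mu1`, `se_mu0`, `ci`, `p`, `weights`, `variance`.
#' @export
ato_inference <- function(ps_model, y, variance = c("stacked", "fixed"),
                          conf = 0.95) {
  variance <- match.arg(variance)
  stopifnot(inherits(ps_model, "ps_model"))
  z <- ps_model$z
  e <- ps_model$ps
  X <- ps_model$X
  w <- overlap_weights(e, z)
  est <- estimate_ato(y, z, w)
  n <- length(y)
  p <- ncol(X)

  r1 <- z * w * (y - est$mu1)
  r0 <- (1 - z) * w * (y - est$mu0)

  if (variance == "stacked") {
    psi <- cbind(X * (z - e), r1, r0)
    B <- crossprod(psi) / n
    A <- matrix(0, p + 2, p + 2)
    A[1:p, 1:p] <- crossprod(X * (e * (1 - e)), X) / n
    # d/dbeta of the weighted-mean equations
    A[p + 1, 1:p] <- colSums(X * (z * e * (1 - e) * (y - est$mu1))) / n
    A[p + 2, 1:p] <- -colSums(X * ((1 - z) * e * (1 - e) * (y - est$mu0))) / n
    A[p + 1, p + 1] <- sum(z * w) / n
    A[p + 2, p + 2] <- sum((1 - z) * w) / n
    kappa <- kappa(A)
    if (!is.finite(kappa) || kappa > 1e12)
      stop("singular bread matrix in sandwich variance (condition number ",
           signif(kappa, 3), ")", call. = FALSE)
    Ainv <- solve(A)
    V <- Ainv %*% B %*% t(Ainv) / n
    vm <- V[(p + 1):(p + 2), (p + 1):(p + 2)]
    var_mu1 <- vm[1, 1]
    var_mu0 <- vm[2, 2]
    var_tau <- vm[1, 1] + vm[2, 2] - 2 * vm[1, 2]
  } else {
    var_mu1 <- sum(r1^2) / sum(z * w)^2
    var_mu0 <- sum(r0^2) / sum((1 - z) * w)^2
    var_tau <- var_mu1 + var_mu0
  }

  se <- sqrt(var_tau)
  zc <- qnorm(1 - (1 - conf) / 2)
  structure(list(
    mu1 = est$mu1, mu0 = est$mu0, tau = est$tau,
    se_tau = se, se_mu1 = sqrt(var_mu1), se_mu0 = sqrt(var_mu0),
    ci = c(est$tau - zc * se, est$tau + zc * se),
    p = 2 * pnorm(-abs(est$tau / se)),
    weights = w, variance = variance), class = "ato_estimate")
}

#' Covariate balance diagnostics
#'
#' Standardized mean differences (SMD) per covariate before and after
#' weighting, and a propensity-score distribution summary per group. With
#' overlap weights from a converged logistic propensity model, the
#' weighted means of every covariate in the model agree between groups
#' exactly (up to solver tolerance) — the exact-balance property.
#'
#' @param data data.frame of covariates.
#' @param covariates covariate column names.
#' @param z 0/1 treatment indicator.
#' @param w weights (unit weights give the unweighted comparison twice).
#' @param ps optional fitted propensity scores for the distribution
#'   summary.
#' @return list with `smd` (data.frame: covariate, unweighted and weighted
#'   arm means, SMDs, weighted mean difference) and `ps_summary`.
#' @export
balance_diagnostics <- function(data, covariates, z, w, ps = NULL) {
  z <- as.numeric(z)
  wmean <- function(x, wt) sum(wt * x) / sum(wt)
  rows <- lapply(covariates, function(v) {
    x <- data[[v]]
    m1 <- mean(x[z == 1]); m0 <- mean(x[z == 0])
    s1 <- var(x[z == 1]); s0 <- var(x[z == 0])
    pool <- sqrt((s1 + s0) / 2)
    wm1 <- wmean(x[z == 1], w[z == 1])
    wm0 <- wmean(x[z == 0], w[z == 0])
    data.frame(covariate = v,
               mean_treated = m1, mean_control = m0,
               smd_unweighted = if (pool > 0) (m1 - m0) / pool else NA_real_,
               wmean_treated = wm1, wmean_control = wm0,
               smd_weighted = if (pool > 0) (wm1 - wm0) / pool else NA_real_,
               wmean_diff = wm1 - wm0)
  })
  ps_summary <- NULL
  if (!is.null(ps)) {
    qs <- c(0, 0.25, 0.5, 0.75, 1)
    ps_summary <- data.frame(
      group = c("intervention", "control"),
      rbind(quantile(ps[z == 1], qs), quantile(ps[z == 0], qs)))
    names(ps_summary)[-1] <- paste0("q", qs * 100)
  }
  list(smd = do.call(rbind, rows), ps_summary = ps_summary)
}
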