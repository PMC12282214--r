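#' Multiple imputation by chained equations with predictive mean matching
#'
#' Fills missing values by iterating over incomplete variables: each is
#' regressed on all other variables (current completed data) among
#' observed cases; regression parameters are drawn from their approximate
#' Bayesian posterior (normal for coefficients, scaled inverse chi-square
#' for the residual variance); missing cases get the posterior-draw
#' prediction, donors keep the least-squares prediction (type-1 matching),
#' and each missing value is replaced by the observed value of one of the
#' `k_donors` donors with the nearest prediction, chosen uniformly.
#' Imputed values are therefore always observed values, preserving each
#' variable's support — including 0/1 codings of categorical variables.
#' The sweep runs `n_iterations` times per dataset and the whole procedure
#' `m` times independently.
#'
#' @param data data.frame of numeric columns (binary variables coded 0/1).
#' @param spec an [imputation_spec()].
#' @param exclude columns never imputed and not used as predictors (ids).
#' @return list of `m` completed data.frames; attribute `"n_missing"`
#'   gives per-variable missing counts.
#' @export
#' @examples
#' d <- data.frame(x = rnorm(50), y = rnorm(50))
#' d$y[1:5] <- NA
#' imp <- impute_pmm(d, imputation_spec(m = 2, seed = 1))
#' length(imp)
impute_pmm <- function(data, spec = imputation_spec(), exclude = "id") {
  set.seed(spec$seed)
  vars <- setdiff(names(data), exclude)
  num <- vars[vapply(data[vars], is.numeric, logical(1))]
  miss <- vapply(data[num], function(x) sum(is.na(x)), integer(1))
  targets <- names(miss)[miss > 0]
  if (any(miss == nrow(data)))
    stop("variable(s) with zero observed cases cannot be imputed: ",
         paste(names(miss)[miss == nrow(data)], collapse = ", "),
         call. = FALSE)
  n_obs_complete <- vapply(data[num], function(x) sum(!is.na(x)), integer(1))
  if (!any(n_obs_complete == nrow(data)) && length(targets) > 0)
    warning("no fully observed predictor available", call. = FALSE)
  targets <- targets[order(miss[targets])]   # least missing first

  M0 <- cbind(`(Intercept)` = 1, as.matrix(data[num]))
  mis_idx <- lapply(targets, function(v) which(is.na(data[[v]])))
  names(mis_idx) <- targets
  col_of <- match(num, colnames(M0))
  names(col_of) <- num

  out <- vector("list", spec$m)
  for (i in seq_len(spec$m)) {
    M <- M0
    # initial fill: random draws from the observed values
    for (v in targets) {
      na <- mis_idx[[v]]
      obs <- M0[-na, col_of[[v]]]
      M[na, col_of[[v]]] <- sample(obs, length(na), replace = TRUE)
    }
    if (length(targets) > 0) {
      for (iter in seq_len(spec$n_iterations)) {
        for (v in targets) {
          na <- mis_idx[[v]]
          j <- col_of[[v]]
          X <- M[, -j, drop = FALSE]
          M[na, j] <- pmm_draw(X[-na, , drop = FALSE], M[-na, j],
                               X[na, , drop = FALSE], spec$k_donors)
        }
      }
    }
    comp <- data
    for (v in targets) comp[[v]] <- M[, col_of[[v]]]
    out[[i]] <- comp
  }
  attr(out, "n_missing") <- miss
  out
}

# one PMM step: Bayesian linear draw + type-1 matching; rank-deficient
# predictor columns are dropped via the pivoted QR
pmm_draw <- function(X_obs, y_obs, X_mis, k) {
  qr_x <- qr(X_obs)
  r <- qr_x$rank
  keep <- qr_x$pivot[seq_len(r)]
  beta_hat <- qr.coef(qr_x, y_obs)[keep]
  yhat_obs <- drop(X_obs[, keep, drop = FALSE] %*% beta_hat)
  res <- y_obs - yhat_obs
  df <- max(length(y_obs) - r, 1)
  sigma2_star <- sum(res^2) / rchisq(1, df)
  # beta* ~ N(beta_hat, sigma2* (X'X)^-1); X'X = R'R on the kept columns
  R <- qr.R(qr_x)[seq_len(r), seq_len(r), drop = FALSE]
  beta_star <- beta_hat + backsolve(R, rnorm(r)) * sqrt(sigma2_star)
  yhat_mis <- drop(X_mis[, keep, drop = FALSE] %*% beta_star)
  match_donors(yhat_obs, y_obs, yhat_mis, k)
}

# for each target prediction, pick uniformly among the k nearest donor
# predictions and return that donor's observed value; the sampled rank is
# resolved by repeated vectorized minimum passes over a candidate window
match_donors <- function(yhat_obs, y_obs, yhat_mis, k) {
  n <- length(yhat_obs)
  k <- min(k, n)
  m <- length(yhat_mis)
  ord <- order(yhat_obs)
  ys <- yhat_obs[ord]
  vs <- y_obs[ord]
  pos <- findInterval(yhat_mis, ys)
  # candidate window of the 2k sorted neighbours around each insertion point
  cand <- outer(pos, seq(-k + 1L, k), "+")
  cand[cand < 1L] <- 1L
  cand[cand > n] <- n
  D <- abs(matrix(ys[cand], m, 2L * k) - yhat_mis)
  # duplicated clamped indices must not be picked twice
  dup <- t(apply(cand, 1L, duplicated))
  D[dup] <- Inf
  rank_pick <- sample.int(k, m, replace = TRUE)
  pick <- integer(m)
  for (pass in seq_len(max(rank_pick))) {
    jmin <- max.col(-D, ties.method = "first")
    hit <- rank_pick == pass
    pick[hit] <- cand[cbind(which(hit), jmin[hit])]
    D[cbind(seq_len(m), jmin)] <- Inf
  }
  vs[pick]
}

#' Pool estimates across imputed datasets by Rubin's rules
#'
#' The pooled estimate is the mean of the per-imputation estimates; the
#' total variance is `T = W + (1 + 1/m) B` where `W` is the mean
#' within-imputation variance and `B` the between-imputation variance of
#' the estimates. Degrees of freedom use the classic large-sample formula
#' `(m - 1) (1 + W / ((1 + 1/m) B))^2` (infinite when `B = 0`), and the
#' confidence interval and p-value use the t reference distribution.
#'
#' @param estimates numeric vector of per-imputation point estimates
#'   (length `m >= 2`).
#' @param variances per-imputation squared standard errors.
#' @param conf confidence level.
#' @return list of class `pooled_estimate` with `estimate`, `W`, `B`, `T`,
#'   `df`, `se`, `ci` (length-2), `p`, `m`.
#' @export
#' @examples
#' pool_rubin(c(1, 3), c(1, 1))  # estimate 2, W 1, B 2, T 4
pool_rubin <- function(estimates, variances, conf = 0.95) {
  m <- length(estimates)
  if (m < 2) stop("Rubin pooling needs m >= 2 estimates", call. = FALSE)
  if (length(variances) != m || any(variances < 0))
    stop("need one non-negative variance per estimate", call. = FALSE)
  est <- mean(estimates)
  W <- mean(variances)
  B <- var(estimates)
  Tv <- W + (1 + 1 / m) * B
  df <- if (B > 0) (m - 1) * (1 + W / ((1 + 1 / m) * B))^2 else Inf
  se <- sqrt(Tv)
  tcrit <- qt(1 - (1 - conf) / 2, df)
  p <- if (se > 0) 2 * pt(-abs(est / se), df) else as.numeric(est == 0)
  structure(list(estimate = est, W = W, B = B, T = Tv, df = df, se = se,
                 ci = c(est - tcrit * se, est + tcrit * se), p = p, m = m),
            class = "pooled_estimate")
}
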