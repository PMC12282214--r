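#' Wear-state transition matrix
#'
#' Builds the first-order Markov transition matrix used to simulate 60-s
#' epoch behavior states during wear time. The chain mixes a "stay" component
#' with a fresh draw from the target occupancy `pi`:
#' `P = mixing * 1 %o% pi + (1 - mixing) * I`, which has stationary
#' distribution exactly `pi` for any `mixing` in (0, 1], while `mixing`
#' controls dwell times (state `i` runs are geometric with continuation
#' probability `1 - mixing * (1 - pi[i])`).
#'
#' @param pi numeric occupancy vector (non-negative, sums to 1), e.g. over
#'   `c(sb, lpa, mvpa)`.
#' @param mixing scalar in (0, 1].
#' @return a `length(pi)` square transition matrix, rows summing to 1.
#' @export
#' @examples
#' P <- transition_matrix(c(0.6, 0.3, 0.1), mixing = 0.25)
#' stationary_distribution(P)
transition_matrix <- function(pi, mixing) {
  if (any(pi < 0) || abs(sum(pi) - 1) > 1e-8)
    stop("`pi` must be a probability vector", call. = FALSE)
  if (mixing <= 0 || mixing > 1)
    stop("`mixing` must be in (0, 1]", call. = FALSE)
  k <- length(pi)
  P <- mixing * matrix(pi, k, k, byrow = TRUE) + (1 - mixing) * diag(k)
  dimnames(P) <- list(names(pi), names(pi))
  P
}

#' Stationary distribution of a transition matrix
#'
#' Left-eigenvector of `P` with eigenvalue 1, normalized to sum to 1.
#'
#' @param P square stochastic matrix (rows sum to 1).
#' @return numeric stationary occupancy vector.
#' @export
stationary_distribution <- function(P) {
  if (any(abs(rowSums(P) - 1) > 1e-8))
    stop("rows of P must sum to 1", call. = FALSE)
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  stats::setNames(pmax(v, 0) / sum(pmax(v, 0)), colnames(P))
}

# simulate n_days parallel chains of n_steps over 3 states with per-day
# occupancy rows `pi` (n_days x 3) and per-day mixing vector; returns an
# integer matrix n_days x n_steps with values 1..3
sim_markov_days <- function(pi, mixing, n_steps) {
  nd <- nrow(pi)
  c1 <- pi[, 1]
  c2 <- pi[, 1] + pi[, 2]
  draw_fresh <- function(n_idx) {
    r <- runif(length(n_idx))
    1L + (r > c1[n_idx]) + (r > c2[n_idx])
  }
  out <- matrix(0L, nd, n_steps)
  out[, 1] <- draw_fresh(seq_len(nd))
  if (n_steps > 1) {
    for (t in 2:n_steps) {
      redraw <- runif(nd) < mixing
      s <- out[, t - 1L]
      if (any(redraw)) s[redraw] <- draw_fresh(which(redraw))
      out[, t] <- s
    }
  }
  out
}
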