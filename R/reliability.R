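#' Null-hypothesis outcome likelihood
#'
#' Under the null hypothesis that no monitored task set matches the current
#' hidden external state, all observed outcome kinds are equally likely, so
#' the null predictive mapping is the constant `1 / n_observed_outcomes`,
#' regardless of stimulus and action.
#'
#' @param n_observed_outcomes Number of distinct outcome values observed so
#'   far (2 in the standard protocols: positive and negative feedback).
#' @return The probability `gamma0`.
#' @export
null_predictive_likelihood <- function(n_observed_outcomes) {
  if (length(n_observed_outcomes) != 1L || is.na(n_observed_outcomes) ||
      n_observed_outcomes < 1) {
    stop("gamma0 is undefined before any outcome has been observed",
         call. = FALSE)
  }
  1 / n_observed_outcomes
}

#' Effective per-trial volatility
#'
#' The perceived volatility `tau` is the per-trial probability that the
#' hidden external state changes. On trials where contextual cues change
#' between two successive trials, the context-sensitivity bias `delta`
#' transiently inflates it by interpolating toward 1:
#' `tau + delta * (1 - tau)`, which stays below 1 for any `delta >= 0`.
#'
#' @param tau Baseline volatility in `(0, 1)`.
#' @param delta Context-sensitivity bias `>= 0` (also capped at 1).
#' @param cue_changed Logical: did the cue change since the previous trial?
#' @return The effective volatility used in the transition model.
#' @export
effective_volatility <- function(tau, delta = 0, cue_changed = FALSE) {
  stopifnot(tau > 0, tau < 1, delta >= 0)
  if (isTRUE(cue_changed)) tau + delta * (1 - tau) else tau
}

#' Hidden-state transition matrix over monitored hypotheses
#'
#' Builds the `(n_states + 1) x (n_states + 1)` stochastic matrix over the
#' monitored task sets plus the null state. Each state keeps its identity
#' with probability `1 - tau_eff` and the escaping mass is spread uniformly
#' over the other states. Entry `[i, j]` is the probability of moving from
#' state `j` to state `i`.
#'
#' @param n_states Number of monitored task sets `N_t >= 1` (the null state
#'   is added internally).
#' @param tau_eff Effective volatility, see [effective_volatility()].
#' @return A column-stochastic transition matrix.
#' @export
transition_matrix <- function(n_states, tau_eff) {
  stopifnot(n_states >= 1, tau_eff >= 0, tau_eff <= 1)
  m <- n_states + 1L
  tm <- matrix(if (m > 1L) tau_eff / (m - 1L) else 0, m, m)
  diag(tm) <- 1 - tau_eff
  tm
}

#' Ex-ante reliability update
#'
#' Propagates the ex-post reliabilities of the previous trial through the
#' volatility transition model, then reweights each hypothesis by the
#' contextual likelihood of the observed cue (task set `i` by its contextual
#' mapping `F_i(cue)`, the null by the neutral baseline `1 / n_cues`), and
#' renormalizes so that `lam0 + sum(lam_i) = 1`.
#'
#' @param buf A [monitoring_buffer] with normalized ex-post reliabilities.
#' @param tau_eff Effective volatility for this trial.
#' @param cue 1-based cue value observed this trial, or `NA` when the
#'   protocol carries no cues.
#' @return The buffer with updated `lam0` and per-set `lam`.
#' @export
update_ex_ante <- function(buf, tau_eff, cue = NA_integer_) {
  n_t <- length(buf$tasksets)
  if (n_t == 0L) {
    buf$lam0 <- 1
    return(buf)
  }
  mu <- c(buf$mu0, buffer_mu(buf))
  lam <- as.vector(transition_matrix(n_t, tau_eff) %*% mu)
  if (!is.na(cue)) {
    w <- vapply(buf$tasksets, function(ts) {
      if (cue > length(ts$contextual)) {
        stop("cue value outside the contextual mapping", call. = FALSE)
      }
      ts$contextual[cue]
    }, 0)
    n_cues <- length(buf$tasksets[[1L]]$contextual)
    lam <- lam * c(1 / n_cues, w)
  }
  lam <- pmax(lam, .prob_floor)
  lam <- lam / sum(lam)
  buf$lam0 <- lam[1L]
  for (i in seq_len(n_t)) buf$tasksets[[i]]$lam <- lam[i + 1L]
  buf
}

#' Ex-post reliability update
#'
#' Bayes step after observing the outcome: each task set's mass is weighted
#' by its predicted likelihood of the observed outcome, `P_i(o | s, a)`, and
#' the null mass by the uniform predictor `gamma0`; the result is
#' renormalized so that `mu0 + sum(mu_i) = 1`.
#'
#' @param buf A [monitoring_buffer] with normalized ex-ante reliabilities.
#' @param s,a,o 1-based stimulus, action and outcome indices.
#' @param gamma0 Null outcome likelihood, see [null_predictive_likelihood()].
#' @return The buffer with updated `mu0` and per-set `mu`.
#' @export
update_ex_post <- function(buf, s, a, o, gamma0) {
  n_t <- length(buf$tasksets)
  lik <- vapply(buf$tasksets, function(ts) {
    if (o > dim(ts$predictive)[3L]) {
      stop("outcome value absent from the predictive mapping", call. = FALSE)
    }
    ts$predictive[s, a, o]
  }, 0)
  mu <- c(buf$lam0 * gamma0, buffer_lam(buf) * lik)
  mu <- pmax(mu, .prob_floor)
  mu <- mu / sum(mu)
  buf$mu0 <- mu[1L]
  for (i in seq_len(n_t)) buf$tasksets[[i]]$mu <- mu[i + 1L]
  buf
}

# Probabilities are floored here before every renormalization so that no
# hypothesis becomes an absorbing zero.
.prob_floor <- 1e-12
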