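#' Epsilon-softmax action policy
#'
#' Converts a row of action values into choice probabilities: a softmax with
#' inverse temperature `beta`, mixed with a uniform lapse floor:
#' `P(a) = (1 - epsilon) * softmax(beta * Q)(a) + epsilon / n_a`.
#'
#' @param q_row Numeric vector of action values (finite).
#' @param beta Inverse temperature `> 0`.
#' @param epsilon Lapse rate in `[0, 1]`.
#' @return Probability vector over actions (sums to 1; every entry at least
#'   `epsilon / n_a`).
#' @export
action_policy <- function(q_row, beta, epsilon = 0) {
  if (any(!is.finite(q_row))) stop("action values must be finite", call. = FALSE)
  stopifnot(length(q_row) >= 2L, beta > 0, epsilon >= 0, epsilon <= 1)
  z <- beta * (q_row - max(q_row))
  p <- exp(z)
  p <- p / sum(p)
  (1 - epsilon) * p + epsilon / length(q_row)
}

#' Delta-rule update of a selective mapping entry
#'
#' `Q <- Q + alpha_s * (r - Q)` for the chosen stimulus-action entry of the
#' actor only; unselected task sets never learn.
#'
#' @param q Current value.
#' @param r Reward value of the observed outcome (1 for positive feedback, 0
#'   for negative, under the default coding).
#' @param alpha_s Learning rate in `(0, 1)`.
#' @return The updated value.
#' @export
update_selective <- function(q, r, alpha_s) {
  q + alpha_s * (r - q)
}

#' Update a predictive mapping row
#'
#' The predictive mapping regularizes the outcome likelihood as a running
#' frequency anchored on its prior: each `(s, a)` cell carries a
#' probability row and an effective observation weight. On an observation
#' the weight grows (with a slow leak, so very old evidence eventually
#' fades) and the row takes a decreasing step toward the indicator of the
#' observed outcome:
#' `w' = (1 - alpha_p) * w + 1`, `P <- P + (1[o] - P) / w'`.
#' Early observations move the row quickly away from its prior; at
#' stationarity the row tracks the long-run outcome frequency (about 0.9
#' for positive feedback on a correct action under 90/10 feedback) with a
#' small variance, instead of chasing recent outcome streaks.
#'
#' @param p_row Probability vector over outcomes for one `(s, a)` cell.
#' @param o 1-based index of the observed outcome.
#' @param alpha_p Leak rate in `(0, 1)`; the stationary effective weight is
#'   `1 / alpha_p`.
#' @param weight Current effective observation weight of the cell (1 for a
#'   fresh cell, counting its prior as one pseudo-observation).
#' @return A list with the updated `p` row and `weight`.
#' @export
update_predictive <- function(p_row, o, alpha_p, weight = 1) {
  one <- numeric(length(p_row))
  one[o] <- 1
  w <- (1 - alpha_p) * weight + 1
  list(p = p_row + (one - p_row) / w, weight = w)
}

#' Random-strategy predictive baseline
#'
#' The outcome prediction of the "random" strategy for any single action:
#' under an injective stimulus-response mapping exactly one of the `n_a`
#' actions is correct, so a priori an action succeeds with probability
#' `1/n_a`. The returned row puts `1/n_a` on the last outcome (positive
#' feedback) and spreads the rest uniformly over the other outcomes. Task
#' sets therefore predict failure for actions they have not learned, which
#' is what makes action outcomes informative about *which* stored mapping
#' is in force.
#'
#' @param n_actions Number of available actions.
#' @param n_outcomes Number of outcome kinds (positive feedback is the last
#'   index).
#' @param prior Success probability assigned to an untried action; defaults
#'   to `1/n_actions`.
#' @return A probability row over outcomes.
#' @export
baseline_predictive <- function(n_actions, n_outcomes = 2L,
                                prior = 1 / n_actions) {
  p <- rep((1 - prior) / (n_outcomes - 1L), n_outcomes)
  p[n_outcomes] <- prior
  p
}

#' Stochastic-gradient update of contextual mappings
#'
#' Contextual mappings learn which cues predict task-set reliability: for
#' the cue observed this trial, every monitored set's entry moves toward its
#' current ex-post reliability, `F(i | C) <- F(i | C) + alpha_c * (mu_i -
#' F(i | C))`.
#'
#' @param f_values Numeric vector `F(i | C)` for the observed cue, one entry
#'   per monitored task set.
#' @param mu Ex-post reliabilities, same length.
#' @param alpha_c Contextual learning rate in `(0, 1)`.
#' @return The updated values.
#' @export
update_contextual <- function(f_values, mu, alpha_c) {
  f_values + alpha_c * (mu - f_values)
}
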