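#' MAX-model actor step
#'
#' The MAX model drops the hypothesis-testing probe phase: the most reliable
#' task set is the actor as long as it beats the null ("random behavior")
#' mass; otherwise a new task set is created and adopted immediately. The
#' new set receives prior reliability equal to the current null level, so it
#' is at once the most reliable hypothesis and its creation is automatically
#' confirmed: there is no probe phase and no discard-on-rival.
#'
#' @param buf A [monitoring_buffer] with current ex-ante reliabilities.
#' @return A list with `action` (`"actor"` or `"create"`) and `actor_id`
#'   (`NA` for `"create"`).
#' @export
max_step <- function(buf) {
  lam <- buffer_lam(buf)
  if (length(lam) && max(lam) >= buf$lam0) {
    ix <- which.max(lam)
    return(list(action = "actor", actor_id = buffer_ids(buf)[ix]))
  }
  list(action = "create", actor_id = NA_integer_)
}

#' Install a MAX-created task set
#'
#' Assigns the new set an ex-ante reliability equal to the current null
#' level and renormalizes all hypotheses, so the newcomer ties the null and
#' dominates every other set.
#'
#' @param buf A [monitoring_buffer].
#' @param ts The new [task_set].
#' @return The updated buffer with the new set as actor.
#' @export
install_max_set <- function(buf, ts) {
  lam_new <- buf$lam0
  ts$lam <- lam_new
  ts$mu <- buf$mu0
  buf$tasksets[[length(buf$tasksets) + 1L]] <- ts
  lam <- c(buf$lam0, buffer_lam(buf))
  mu <- c(buf$mu0, buffer_mu(buf))
  lam <- lam / sum(lam)
  mu <- mu / sum(mu)
  buf$lam0 <- lam[1L]; buf$mu0 <- mu[1L]
  for (i in seq_along(buf$tasksets)) {
    buf$tasksets[[i]]$lam <- lam[i + 1L]
    buf$tasksets[[i]]$mu <- mu[i + 1L]
  }
  buf$actor_id <- ts$id
  buf
}

#' FORGET-model strategy decay
#'
#' Strategies of unused task sets decay toward the random (uniform)
#' strategy at rate `phi`: every mapping `T <- (1 - phi) * T + phi * U`, so
#' the distance to uniform contracts geometrically by `(1 - phi)` per trial.
#' `phi = 0` recovers the multiple-actor special case (no decay).
#'
#' @param tbl A numeric matrix or array (selective or predictive mapping).
#' @param phi Decay rate in `[0, 1]`.
#' @param uniform_value Value of the uniform strategy for this table
#'   (`1/n_actions` for selective mappings, `1/n_outcomes` for predictive).
#' @return The decayed table.
#' @export
forget_decay <- function(tbl, phi, uniform_value) {
  stopifnot(phi >= 0, phi <= 1)
  (1 - phi) * tbl + phi * uniform_value
}

#' FORGET-model actor choice
#'
#' With a fixed collection of task sets and no creation, the actor is drawn
#' by a softmax over ex-ante reliabilities with inverse temperature
#' `beta_actor`.
#'
#' @param lam Ex-ante reliabilities of the monitored sets.
#' @param beta_actor Actor-choice inverse temperature `>= 0`.
#' @return Probability vector over the sets.
#' @export
forget_actor_choice <- function(lam, beta_actor) {
  stopifnot(beta_actor >= 0)
  z <- beta_actor * (lam - max(lam))
  p <- exp(z)
  p / sum(p)
}

#' Reliability-weighted learning step (FORGET model)
#'
#' In the FORGET model every task set learns concurrently, in proportion to
#' its ex-post reliability: set `i` takes a delta-rule step with effective
#' rate `alpha_s * mu_i`.
#'
#' @param q_values Current values of the updated `(s, a)` entry, one per set.
#' @param mu Ex-post reliabilities, same length.
#' @param r Reward value of the observed outcome.
#' @param alpha_s Base learning rate.
#' @return Updated values.
#' @export
forget_weighted_learning <- function(q_values, mu, r, alpha_s) {
  q_values + alpha_s * mu * (r - q_values)
}

#' Flat reinforcement-learning policy
#'
#' The baseline RL models hold no task sets: a single actor learns
#' stimulus-response values (and, with cues, stimulus-cue-response values)
#' by the delta rule. The policy is an epsilon-softmax over the mixed values
#' `Q_mix = (1 - omega) * Q_SR(s, .) + omega * Q_SCR(s, cue, .)`. With
#' `omega = 0` this is the plain stimulus-response RL baseline.
#'
#' @param q_sr `n_stimuli x n_actions` stimulus-response value matrix.
#' @param s 1-based stimulus.
#' @param beta,epsilon Policy parameters, see [action_policy()].
#' @param omega Mixture rate in `[0, 1]`.
#' @param q_scr Optional `n_stimuli x n_cues x n_actions` array (required
#'   when `omega > 0`).
#' @param cue 1-based cue (required when `omega > 0`).
#' @return Probability vector over actions.
#' @export
rl_policy <- function(q_sr, s, beta, epsilon = 0, omega = 0, q_scr = NULL,
                      cue = NA_integer_) {
  stopifnot(omega >= 0, omega <= 1)
  q <- q_sr[s, ]
  if (omega > 0) {
    if (is.null(q_scr) || is.na(cue)) {
      stop("a cue and a stimulus-cue-response table are required when omega > 0",
           call. = FALSE)
    }
    q <- (1 - omega) * q + omega * q_scr[s, cue, ]
  }
  action_policy(q, beta, epsilon)
}
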