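#' Model parameter sets
#'
#' Constructors for the parameter lists accepted by [simulate_agent()] and
#' the fitting functions. Bounds are checked on construction.
#'
#' Shared action-policy and learning parameters: inverse temperature `beta`
#' (> 0), lapse rate `epsilon` in `[0, 1]`, selective learning rate
#' `alpha_s` in `(0, 1)`, predictive outcome-frequency smoothing rate
#' `alpha_p` (slow by default, so outcome predictions regularize toward the
#' long-run feedback frequencies instead of chasing recent streaks),
#' contextual learning rate `alpha_c` in `(0, 1)`, perceived per-trial
#' volatility `tau` in `(0, 1)` and context-sensitivity bias `delta >= 0`.
#' Positive feedback carries reward value 1, negative 0.
#'
#' @param n Monitoring capacity `N >= 1`.
#' @param beta,epsilon,alpha_s,alpha_p,alpha_c,tau,delta See details.
#' @param eta Recollection entropy in `[0, 1]` (PROBE and MAX).
#' @param theta Confirmation bias in `[0, 1]` (PROBE only).
#' @param phi Decay rate in `[0, 1]` (FORGET only).
#' @param beta_actor Actor-choice inverse temperature `>= 0` (FORGET only).
#' @param learning `"weighted"` (reliability-proportional learning in every
#'   set) or `"actor"` (actor-only learning) for the FORGET model.
#' @param omega Mixture rate in `[0, 1]` between stimulus-response and
#'   stimulus-cue-response values (RL only).
#' @param pred_prior Success probability a task set assigns to an action it
#'   has not tried (the random-strategy baseline, see
#'   [baseline_predictive()]); default `1/n_actions` for the standard
#'   4-action protocols.
#' @param pred_weight0 Initial effective observation weight of each
#'   predictive cell (how strongly the baseline resists the first
#'   observations).
#' @return A named list of class `agent_params` with a `model` field.
#' @export
probe_params <- function(n = 3, beta = 30, epsilon = 0, alpha_s = 0.4,
                         alpha_p = 0.02, alpha_c = 0.1, eta = 1,
                         theta = 0, tau = 0.03, delta = 0,
                         pred_prior = 0.25, pred_weight0 = 2) {
  check_shared(beta, epsilon, alpha_s, alpha_p, alpha_c, tau, delta)
  stopifnot(n >= 1, eta >= 0, eta <= 1, theta >= 0, theta <= 1,
            pred_prior > 0, pred_prior < 1, pred_weight0 > 0)
  structure(list(model = "probe", n = as.integer(n), beta = beta,
                 epsilon = epsilon, alpha_s = alpha_s, alpha_p = alpha_p,
                 alpha_c = alpha_c, eta = eta, theta = theta, tau = tau,
                 delta = delta, pred_prior = pred_prior,
                 pred_weight0 = pred_weight0), class = "agent_params")
}

#' @rdname probe_params
#' @export
max_params <- function(n = 3, beta = 30, epsilon = 0, alpha_s = 0.4,
                       alpha_p = 0.02, alpha_c = 0.1, eta = 1,
                       tau = 0.03, delta = 0, pred_prior = 0.25,
                       pred_weight0 = 2) {
  p <- probe_params(n, beta, epsilon, alpha_s, alpha_p, alpha_c, eta,
                    theta = 0, tau = tau, delta = delta,
                    pred_prior = pred_prior, pred_weight0 = pred_weight0)
  p$model <- "max"
  p
}

#' @rdname probe_params
#' @export
forget_params <- function(n = 2, beta = 30, epsilon = 0, alpha_s = 0.4,
                          alpha_p = 0.02, alpha_c = 0.1, phi = 0.14,
                          beta_actor = 30, tau = 0.03, delta = 0,
                          learning = c("weighted", "actor"),
                          pred_prior = 0.25, pred_weight0 = 2) {
  check_shared(beta, epsilon, alpha_s, alpha_p, alpha_c, tau, delta)
  stopifnot(n >= 1, phi >= 0, phi <= 1, beta_actor >= 0, pred_prior > 0,
            pred_prior < 1, pred_weight0 > 0)
  learning <- match.arg(learning)
  structure(list(model = "forget", n = as.integer(n), beta = beta,
                 epsilon = epsilon, alpha_s = alpha_s, alpha_p = alpha_p,
                 alpha_c = alpha_c, phi = phi, beta_actor = beta_actor,
                 tau = tau, delta = delta, learning = learning,
                 pred_prior = pred_prior, pred_weight0 = pred_weight0),
            class = "agent_params")
}

#' @rdname probe_params
#' @export
rl_params <- function(beta = 30, epsilon = 0, alpha_s = 0.4, omega = 0,
                      alpha_c = 0.1) {
  stopifnot(beta > 0, epsilon >= 0, epsilon <= 1, alpha_s > 0, alpha_s < 1,
            omega >= 0, omega <= 1, alpha_c > 0, alpha_c < 1)
  structure(list(model = "rl", beta = beta, epsilon = epsilon,
                 alpha_s = alpha_s, omega = omega, alpha_c = alpha_c),
            class = "agent_params")
}

check_shared <- function(beta, epsilon, alpha_s, alpha_p, alpha_c, tau, delta) {
  stopifnot(beta > 0, epsilon >= 0, epsilon <= 1, alpha_s > 0, alpha_s < 1,
            alpha_p > 0, alpha_p < 1, alpha_c > 0, alpha_c < 1,
            tau > 0, tau < 1, delta >= 0, delta <= 1)
  invisible(TRUE)
}
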