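# Shared test helpers: independent forward-filter oracle and tiny builders.

# Build a task set whose predictive mapping has P(positive | s, a) given by
# the matrix `p_pos` (positive feedback = outcome index 2).
make_ts <- function(id, p_pos, lam = 0, mu = 0, n_cues = 0L,
                    contextual = NULL, last = 0L) {
  n_s <- nrow(p_pos); n_a <- ncol(p_pos)
  pred <- array(0, dim = c(n_s, n_a, 2L))
  pred[, , 2L] <- p_pos
  pred[, , 1L] <- 1 - p_pos
  task_set(id, n_s, n_a, 2L, n_cues, predictive = pred, lam = lam, mu = mu,
           contextual = contextual, last_actor_trial = last)
}

# Exact forward algorithm on the equivalent hidden Markov model, written
# directly: full transition-matrix products and explicit normalization.
# States: null first, then the task sets. `lik[t, ]` is the outcome
# likelihood of each state on trial t; `ctx_lik[t, ]` the cue likelihood
# (all-ones when absent). Returns the lambda (pre-outcome) and mu
# (post-outcome) trajectories.
oracle_forward <- function(mu0, tau_seq, lik, ctx_lik = NULL) {
  n_states <- length(mu0)
  n_trials <- nrow(lik)
  if (is.null(ctx_lik)) ctx_lik <- matrix(1, n_trials, n_states)
  lam_out <- matrix(NA_real_, n_trials, n_states)
  mu_out <- matrix(NA_real_, n_trials, n_states)
  mu <- mu0
  for (t in seq_len(n_trials)) {
    tm <- matrix(tau_seq[t] / (n_states - 1), n_states, n_states)
    diag(tm) <- 1 - tau_seq[t]
    lam <- as.vector(tm %*% mu)
    lam <- lam * ctx_lik[t, ]
    lam <- lam / sum(lam)
    mu <- lam * lik[t, ]
    mu <- mu / sum(mu)
    lam_out[t, ] <- lam
    mu_out[t, ] <- mu
  }
  list(lam = lam_out, mu = mu_out)
}

# A minimal stationary protocol (single episode, cycling stimuli).
stationary_protocol <- function(n_trials, mapping = c(1L, 2L, 3L),
                                condition = "open") {
  stim <- rep_len(seq_along(mapping), n_trials)
  structure(list(
    experiment = "toy", session_id = "toy", n_stimuli = length(mapping),
    n_actions = 4L, n_cues = 0L, seed = NA_integer_,
    mappings = matrix(mapping, 1L),
    episodes = data.frame(episode = 1L, mapping = 1L, length = n_trials,
                          condition = condition),
    trials = data.frame(episode_index = 1L,
                        trial_in_episode = seq_len(n_trials) - 1L,
                        stimulus = stim, cue = NA_integer_,
                        correct_response = mapping[stim],
                        condition = condition)),
    class = "session_protocol")
}
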