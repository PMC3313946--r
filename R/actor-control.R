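#' Satisficing actor selection
#'
#' A task set whose ex-ante reliability exceeds 0.5 is more likely reliable
#' than unreliable; normalization guarantees that at most one set can meet
#' this criterion, and that set becomes the actor. When none meets it, an
#' active probe stays in charge; with no probe, a new task set must be
#' created and probed.
#'
#' @param buf A [monitoring_buffer] with current ex-ante reliabilities.
#' @return A list with `action` (`"actor"`, `"continue_probe"` or
#'   `"create"`) and `actor_id` (`NA` for `"create"`).
#' @export
select_actor <- function(buf) {
  lam <- buffer_lam(buf)
  ids <- buffer_ids(buf)
  above <- which(lam > 0.5)
  if (length(above) == 1L) {
    return(list(action = "actor", actor_id = ids[above]))
  }
  if (!is.na(buf$probe_id)) {
    return(list(action = "continue_probe", actor_id = buf$probe_id))
  }
  list(action = "create", actor_id = NA_integer_)
}

#' Create a probe task set from long-term memory
#'
#' The new selective and predictive mappings are a convex mixture of all
#' strategies stored in long-term memory and the random strategy `U`:
#' `M_new = (1 - eta) * sum_k w_k * M_k + eta * U`, where the recollection
#' weights `w_k` are proportional to the contextual likelihood of strategy
#' `k` given the current cue (uniform when no cue is observed or no
#' contextual evidence exists). The recollection entropy `eta` scales
#' recollection noise: `eta = 1` ignores memory entirely, `eta = 0` is a
#' noiseless recollection. With an empty store the probe is the pure random
#' strategy (cold start): uniform action values and the
#' [baseline_predictive()] outcome prediction. The probe's contextual
#' mapping starts at the neutral baseline and its predictive confidence
#' weights are reset (recollection restores content, not confidence).
#'
#' @param ltm A [long_term_memory].
#' @param id Integer id for the new set.
#' @param eta Recollection entropy in `[0, 1]`.
#' @param cue 1-based cue value or `NA`.
#' @param n_stimuli,n_actions,n_outcomes,n_cues Mapping dimensions.
#' @param trial Current trial index (recorded as `last_actor_trial`).
#' @param pred_prior Untried-action success prior of the random strategy,
#'   see [baseline_predictive()].
#' @return A new [task_set] (reliabilities left at 0; the caller assigns the
#'   prior through [prior_reliability()] / [apply_confirmation_bias()]).
#' @export
create_probe <- function(ltm, id, eta, cue = NA_integer_, n_stimuli = 3L,
                         n_actions = 4L, n_outcomes = 2L, n_cues = 0L,
                         trial = 0L, pred_prior = 1 / n_actions) {
  stopifnot(eta >= 0, eta <= 1)
  u_sel <- matrix(1 / n_actions, n_stimuli, n_actions)
  u_pred <- array(rep(baseline_predictive(n_actions, n_outcomes, pred_prior),
                      each = n_stimuli * n_actions),
                  dim = c(n_stimuli, n_actions, n_outcomes))
  k <- ltm_size(ltm)
  if (k == 0L || eta == 1) {
    sel <- u_sel
    pred <- u_pred
  } else {
    w <- if (!is.na(cue)) {
      vapply(ltm$strategies, function(st) st$contextual[cue], 0)
    } else {
      rep(1, k)
    }
    if (sum(w) <= 0) w <- rep(1, k)
    w <- w / sum(w)
    sel <- matrix(0, n_stimuli, n_actions)
    pred <- array(0, dim = c(n_stimuli, n_actions, n_outcomes))
    for (j in seq_len(k)) {
      sel <- sel + w[j] * ltm$strategies[[j]]$selective
      pred <- pred + w[j] * ltm$strategies[[j]]$predictive
    }
    sel <- (1 - eta) * sel + eta * u_sel
    pred <- (1 - eta) * pred + eta * u_pred
  }
  task_set(id = id, n_stimuli = n_stimuli, n_actions = n_actions,
           n_outcomes = n_outcomes, n_cues = n_cues, selective = sel,
           predictive = pred, lam = 0, mu = 0, last_actor_trial = trial)
}

#' Maximum-entropy prior reliability of a new probe
#'
#' A freshly created probe carries no evidence about its own reliability, so
#' its prior is chosen to minimize prior information: it maximizes the
#' entropy of the reliability distribution. With `H` the Shannon entropy (in
#' nats) of the renormalized ex-ante reliabilities of the other monitored
#' task sets, the maximizing prior is `1 / (2 + exp(H))`. Since
#' `0 <= H <= log(N_t - 1)`, the prior always lies in
#' `[1 / (N_t + 1), 1/3]` (with `N_t` counting the probe itself), so a fresh
#' probe never immediately meets the `lam > 0.5` selection criterion.
#'
#' @param lam_others Ex-ante reliabilities of the other monitored task sets
#'   (excluding the probe and the null); may be empty.
#' @return The prior reliability `lam_prior`.
#' @export
prior_reliability <- function(lam_others = numeric(0)) {
  lam_others <- lam_others[lam_others > 0]
  h <- 0
  if (length(lam_others) > 1L) {
    p <- lam_others / sum(lam_others)
    h <- -sum(p * log(p))
  }
  1 / (2 + exp(h))
}

#' Confirmation bias on the probe prior
#'
#' Interpolates the maximum-entropy prior toward the 0.5 selection
#' threshold: `(1 - theta) * lam_prior + theta * 0.5`. A large bias makes
#' the agent reluctant to abandon a newly created probe.
#'
#' @param lam_prior Prior reliability from [prior_reliability()].
#' @param theta Confirmation bias in `[0, 1]`.
#' @return The biased prior (never above 0.5).
#' @export
apply_confirmation_bias <- function(lam_prior, theta) {
  stopifnot(theta >= 0, theta <= 1)
  (1 - theta) * lam_prior + theta * 0.5
}

#' Install a probe task set in the buffer
#'
#' Appends the probe, assigns it the biased maximum-entropy prior, and
#' rescales the remaining hypotheses (other sets and the null) by
#' `1 - lam_prior` so the ex-ante distribution stays normalized.
#'
#' @param buf A [monitoring_buffer].
#' @param probe A [task_set] built by [create_probe()].
#' @param theta Confirmation bias.
#' @return The updated buffer, with `probe_id` and `actor_id` set.
#' @export
install_probe <- function(buf, probe, theta = 0) {
  lam_prior <- apply_confirmation_bias(prior_reliability(buffer_lam(buf)), theta)
  scale <- 1 - lam_prior
  buf$lam0 <- buf$lam0 * scale
  for (i in seq_along(buf$tasksets)) {
    buf$tasksets[[i]]$lam <- buf$tasksets[[i]]$lam * scale
  }
  probe$lam <- lam_prior
  buf$tasksets[[length(buf$tasksets) + 1L]] <- probe
  buf$probe_id <- probe$id
  buf$actor_id <- probe$id
  validate_buffer(buf)
  buf
}

#' Resolve the probe phase
#'
#' The probe phase terminates when either hypothesis test concludes:
#' `"confirm"` when the probe itself becomes reliable (`lam > 0.5`) while
#' all other sets stay unreliable — its strategy then belongs in long-term
#' memory; `"discard"` when another set becomes reliable first — the probe
#' is removed without leaving any trace in memory and the winner becomes the
#' actor; `"continue"` otherwise.
#'
#' @param buf A [monitoring_buffer] with an active probe.
#' @return One of `"confirm"`, `"discard"`, `"continue"`.
#' @export
resolve_probe <- function(buf) {
  if (is.na(buf$probe_id)) stop("no active probe", call. = FALSE)
  ix <- buffer_index(buf, buf$probe_id)
  lam <- buffer_lam(buf)
  lam_probe <- lam[ix]
  lam_rest <- lam[-ix]
  if (lam_probe > 0.5) return("confirm")
  if (length(lam_rest) && max(lam_rest) > 0.5) return("discard")
  "continue"
}

#' Remove a task set from the buffer
#'
#' Drops the set and renormalizes the remaining reliability mass
#' proportionally (used for probe discard and LRU eviction).
#'
#' @param buf A [monitoring_buffer].
#' @param id Id of the set to remove.
#' @return The updated buffer.
#' @export
drop_taskset <- function(buf, id) {
  ix <- buffer_index(buf, id)
  buf$tasksets[[ix]] <- NULL
  lam <- c(buf$lam0, buffer_lam(buf))
  mu <- c(buf$mu0, buffer_mu(buf))
  lam <- pmax(lam, .prob_floor); lam <- lam / sum(lam)
  mu <- pmax(mu, .prob_floor); mu <- mu / sum(mu)
  buf$lam0 <- lam[1L]
  buf$mu0 <- mu[1L]
  for (i in seq_along(buf$tasksets)) {
    buf$tasksets[[i]]$lam <- lam[i + 1L]
    buf$tasksets[[i]]$mu <- mu[i + 1L]
  }
  if (!is.na(buf$probe_id) && buf$probe_id == id) buf$probe_id <- NA_integer_
  if (!is.na(buf$actor_id) && buf$actor_id == id) buf$actor_id <- NA_integer_
  buf
}

#' Evict the least recently used task set when over capacity
#'
#' After a probe confirmation the buffer may transiently hold `N + 1` sets;
#' the set that acted least recently (ties broken by smallest id) is then
#' evicted. Its strategy is refreshed in long-term memory first, so it
#' remains recollectable through [create_probe()].
#'
#' @param buf A [monitoring_buffer].
#' @param ltm A [long_term_memory].
#' @return A list with the updated `buf` and `ltm`.
#' @export
evict_if_full <- function(buf, ltm) {
  if (length(buf$tasksets) <= buf$capacity) {
    return(list(buf = buf, ltm = ltm))
  }
  last <- vapply(buf$tasksets, `[[`, 0L, "last_actor_trial")
  ids <- buffer_ids(buf)
  cand <- which(last == min(last))
  victim <- cand[which.min(ids[cand])]
  ltm <- ltm_store(ltm, buf$tasksets[[victim]])
  buf <- drop_taskset(buf, ids[victim])
  list(buf = buf, ltm = ltm)
}
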