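#' Simulate an agent on a session protocol
#'
#' Runs one of the four model families (PROBE, MAX, FORGET, flat RL) over
#' the trial schedule of a `session_protocol`, sampling actions from the
#' model policy and 90/10 probabilistic feedback from the environment.
#'
#' Two engines produce identical trajectories for a given seed: the
#' compiled engine (default, used for large simulation studies and fitting)
#' and a pure-R reference engine composed from the exported per-operation
#' functions (used for cross-validation in the test suite).
#'
#' @param params An `agent_params` object, see [probe_params()].
#' @param protocol A `session_protocol`.
#' @param seed Optional integer seed set before the run.
#' @param engine `"cpp"` (compiled) or `"r"` (reference).
#' @param p_feedback Positive-feedback probability for correct actions.
#' @return A behavioral log `data.frame` with one row per trial: columns
#'   `session_id`, `condition`, `episode_index`, `trial_in_episode`,
#'   `stimulus`, `cue`, `response`, `outcome` (1 = positive feedback),
#'   `correct_response`, `is_correct`, `is_perseverative`, `seed`.
#' @export
simulate_agent <- function(params, protocol, seed = NULL,
                           engine = c("cpp", "r"), p_feedback = 0.9) {
  engine <- match.arg(engine)
  if (!is.null(seed)) set.seed(seed)
  tr <- protocol$trials
  res <- run_engine(params, protocol, mode = "simulate", engine = engine,
                    p_feedback = p_feedback)
  log <- data.frame(
    session_id = protocol$session_id,
    condition = tr$condition,
    episode_index = tr$episode_index,
    trial_in_episode = tr$trial_in_episode,
    stimulus = tr$stimulus,
    cue = tr$cue,
    response = res$response,
    outcome = res$outcome,
    correct_response = tr$correct_response,
    stringsAsFactors = FALSE)
  log$is_correct <- as.integer(log$response == log$correct_response)
  log$is_perseverative <- perseverative_flags(log)
  log$seed <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  log
}

#' Evaluate one-step-ahead response probabilities on a behavioral log
#'
#' Evolves the model by conditioning on the log's actual responses and
#' outcomes and returns, for every trial, the predicted probability of the
#' response actually produced and of the correct response. For the FORGET
#' model, whose actor choice is stochastic, the response probability is the
#' marginal over actors and the internal decay is applied in expectation.
#'
#' @inheritParams simulate_agent
#' @param log A behavioral log with `stimulus`, `cue`, `response`,
#'   `outcome`, `correct_response` columns.
#' @return A list with numeric vectors `p_response` and `p_correct`.
#' @export
predict_agent <- function(params, log, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  protocol <- protocol_from_log(log)
  run_engine(params, protocol, mode = "predict", engine = engine,
             response = log$response, outcome = log$outcome)
}

# Minimal protocol view reconstructed from a log (enough for the engines).
protocol_from_log <- function(log) {
  n_cues <- if (all(is.na(log$cue))) 0L else max(log$cue, na.rm = TRUE)
  list(trials = log,
       n_stimuli = max(log$stimulus), n_actions = 4L, n_cues = n_cues,
       session_id = log$session_id[1L])
}

run_engine <- function(params, protocol, mode, engine, p_feedback = 0.9,
                       response = NULL, outcome = NULL) {
  tr <- protocol$trials
  cue <- tr$cue
  cue[is.na(cue)] <- 0L
  predict_mode <- mode == "predict"
  if (engine == "cpp") {
    model_code <- match(params$model, c("probe", "max", "forget", "rl")) - 1L
    out <- cpp_agent_engine(
      as.integer(tr$stimulus), as.integer(cue),
      as.integer(tr$correct_response),
      as.integer(protocol$n_stimuli), as.integer(protocol$n_actions), 2L,
      as.integer(protocol$n_cues), params, model_code, predict_mode,
      if (predict_mode) as.integer(response) else integer(0),
      if (predict_mode) as.integer(outcome) else integer(0),
      p_feedback)
  } else {
    out <- switch(params$model,
      probe = ,
      max = r_probe_engine(tr, cue, protocol, params, predict_mode,
                           response, outcome, p_feedback),
      forget = r_forget_engine(tr, cue, protocol, params, predict_mode,
                               response, outcome, p_feedback),
      rl = r_rl_engine(tr, cue, protocol, params, predict_mode,
                       response, outcome, p_feedback))
  }
  out
}

# single draw from a probability vector using one uniform variate; the
# compiled engine uses the same construction so seeded trajectories match
draw_categorical <- function(p) {
  u <- stats::runif(1)
  cs <- cumsum(p)
  for (i in seq_along(cs)) if (u < cs[i]) return(i)
  length(p)
}

# ---- pure-R reference engines -------------------------------------------

r_probe_engine <- function(tr, cue, protocol, params, predict_mode,
                           response, outcome, p_feedback) {
  n_s <- protocol$n_stimuli; n_a <- protocol$n_actions; n_o <- 2L
  n_c <- protocol$n_cues
  is_max <- params$model == "max"
  n_trials <- nrow(tr)
  buf <- monitoring_buffer(params$n)
  ltm <- long_term_memory()
  p0 <- baseline_predictive(n_a, n_o, params$pred_prior)
  p0_arr <- array(rep(p0, each = n_s * n_a), dim = c(n_s, n_a, n_o))
  w0 <- params$pred_weight0
  next_id <- 1L
  seen <- logical(n_o)
  resp <- integer(n_trials); out <- integer(n_trials)
  p_resp <- numeric(n_trials); p_corr <- numeric(n_trials)
  n_created <- 0L

  for (t in seq_len(n_trials)) {
    s <- tr$stimulus[t]
    cu <- if (cue[t] > 0L) cue[t] else NA_integer_
    cue_changed <- t > 1L && cue[t] > 0L && cue[t - 1L] > 0L &&
      cue[t] != cue[t - 1L]
    tt <- effective_volatility(params$tau, params$delta, cue_changed)
    buf <- update_ex_ante(buf, tt, cu)

    if (!is_max && !is.na(buf$probe_id)) {
      res <- resolve_probe(buf)
      if (res == "confirm") {
        ix <- buffer_index(buf, buf$probe_id)
        ltm <- ltm_store(ltm, buf$tasksets[[ix]])
        buf$probe_id <- NA_integer_
        ev <- evict_if_full(buf, ltm)
        buf <- ev$buf; ltm <- ev$ltm
      } else if (res == "discard") {
        buf <- drop_taskset(buf, buf$probe_id)
      }
    }

    sel <- if (is_max) max_step(buf) else select_actor(buf)
    if (sel$action == "create") {
      ts <- create_probe(ltm, next_id, params$eta, cu, n_s, n_a, n_o, n_c,
                         trial = t, pred_prior = params$pred_prior)
      ts$pred_weight[] <- w0
      next_id <- next_id + 1L
      n_created <- n_created + 1L
      if (is_max) {
        buf <- install_max_set(buf, ts)
        ltm <- ltm_store(ltm, ts)
        ev <- evict_if_full(buf, ltm)
        buf <- ev$buf; ltm <- ev$ltm
      } else {
        buf <- install_probe(buf, ts, params$theta)
      }
    } else {
      buf$actor_id <- sel$actor_id
    }
    ai <- buffer_index(buf, buf$actor_id)
    buf$tasksets[[ai]]$last_actor_trial <- t

    pol <- action_policy(buf$tasksets[[ai]]$selective[s, ], params$beta,
                         params$epsilon)
    if (predict_mode) {
      a <- response[t]
      o <- outcome[t]
    } else {
      a <- draw_categorical(pol)
      p_pos <- if (a == tr$correct_response[t]) p_feedback else 1 - p_feedback
      o <- as.integer(stats::runif(1) < p_pos)
    }
    p_resp[t] <- pol[a]
    p_corr[t] <- pol[tr$correct_response[t]]
    resp[t] <- a; out[t] <- o

    o_idx <- o + 1L
    seen[o_idx] <- TRUE
    gamma0 <- null_predictive_likelihood(sum(seen))
    buf <- update_ex_post(buf, s, a, o_idx, gamma0)

    buf$tasksets[[ai]]$selective[s, a] <-
      update_selective(buf$tasksets[[ai]]$selective[s, a], o, params$alpha_s)
    upd <- update_predictive(buf$tasksets[[ai]]$predictive[s, a, ], o_idx,
                             params$alpha_p,
                             buf$tasksets[[ai]]$pred_weight[s, a])
    buf$tasksets[[ai]]$predictive[s, a, ] <- upd$p
    buf$tasksets[[ai]]$pred_weight[s, a] <- upd$weight
    if (!is.na(cu)) {
      mu <- buffer_mu(buf)
      for (i in seq_along(buf$tasksets)) {
        buf$tasksets[[i]]$contextual[cu] <-
          update_contextual(buf$tasksets[[i]]$contextual[cu], mu[i],
                            params$alpha_c)
      }
    }
  }
  list(response = resp, outcome = out, p_response = p_resp,
       p_correct = p_corr, n_created = n_created)
}

r_forget_engine <- function(tr, cue, protocol, params, predict_mode,
                            response, outcome, p_feedback) {
  n_s <- protocol$n_stimuli; n_a <- protocol$n_actions; n_o <- 2L
  n_c <- protocol$n_cues
  n <- params$n
  n_trials <- nrow(tr)
  p0 <- baseline_predictive(n_a, n_o, params$pred_prior)
  p0_arr <- array(rep(p0, each = n_s * n_a), dim = c(n_s, n_a, n_o))
  sets <- lapply(seq_len(n), function(i) {
    s <- task_set(i, n_s, n_a, n_o, n_c, predictive = p0_arr,
                  lam = 1 / (n + 1), mu = 1 / (n + 1))
    s$pred_weight[] <- params$pred_weight0
    s
  })
  buf <- monitoring_buffer(n, sets)
  seen <- logical(n_o)
  resp <- integer(n_trials); out <- integer(n_trials)
  p_resp <- numeric(n_trials); p_corr <- numeric(n_trials)
  weighted <- params$learning == "weighted"

  for (t in seq_len(n_trials)) {
    s <- tr$stimulus[t]
    cu <- if (cue[t] > 0L) cue[t] else NA_integer_
    cue_changed <- t > 1L && cue[t] > 0L && cue[t - 1L] > 0L &&
      cue[t] != cue[t - 1L]
    tt <- effective_volatility(params$tau, params$delta, cue_changed)
    buf <- update_ex_ante(buf, tt, cu)

    w <- forget_actor_choice(buffer_lam(buf), params$beta_actor)
    if (predict_mode) {
      pol <- rep(0, n_a)
      for (k in seq_len(n)) {
        pol <- pol + w[k] * action_policy(buf$tasksets[[k]]$selective[s, ],
                                          params$beta, params$epsilon)
      }
      a <- response[t]; o <- outcome[t]
      actor <- NA_integer_
    } else {
      actor <- if (n == 1L) 1L else draw_categorical(w)
      pol <- action_policy(buf$tasksets[[actor]]$selective[s, ], params$beta,
                           params$epsilon)
      a <- draw_categorical(pol)
      p_pos <- if (a == tr$correct_response[t]) p_feedback else 1 - p_feedback
      o <- as.integer(stats::runif(1) < p_pos)
    }
    p_resp[t] <- pol[a]
    p_corr[t] <- pol[tr$correct_response[t]]
    resp[t] <- a; out[t] <- o

    o_idx <- o + 1L
    seen[o_idx] <- TRUE
    gamma0 <- null_predictive_likelihood(sum(seen))
    buf <- update_ex_post(buf, s, a, o_idx, gamma0)

    mu <- buffer_mu(buf)
    for (k in seq_len(n)) {
      # reliability-weighted learning: set k takes a delta step scaled by
      # mu_k (weighted mode) or the actor learns alone at full rate
      step <- if (weighted) mu[k]
              else if (!is.na(actor) && k == actor) 1 else 0
      if (step > 0) {
        buf$tasksets[[k]]$selective[s, a] <-
          update_selective(buf$tasksets[[k]]$selective[s, a], o,
                           params$alpha_s * step)
        wk <- (1 - params$alpha_p) * buf$tasksets[[k]]$pred_weight[s, a] + step
        one <- numeric(n_o); one[o_idx] <- 1
        buf$tasksets[[k]]$predictive[s, a, ] <-
          buf$tasksets[[k]]$predictive[s, a, ] +
          step * (one - buf$tasksets[[k]]$predictive[s, a, ]) / wk
        buf$tasksets[[k]]$pred_weight[s, a] <- wk
      }
    }
    # decay of unused strategies toward the random strategy; in predict
    # mode (marginal actor) each set decays by its expected non-actor share
    for (k in seq_len(n)) {
      phi_k <- if (predict_mode) params$phi * (1 - w[k])
               else if (!is.na(actor) && k == actor) 0 else params$phi
      if (phi_k > 0) {
        buf$tasksets[[k]]$selective <-
          forget_decay(buf$tasksets[[k]]$selective, phi_k, 1 / n_a)
        buf$tasksets[[k]]$predictive <-
          (1 - phi_k) * buf$tasksets[[k]]$predictive + phi_k * p0_arr
        buf$tasksets[[k]]$pred_weight <-
          (1 - phi_k) * buf$tasksets[[k]]$pred_weight + phi_k
      }
    }
    if (!is.na(cu)) {
      mu <- buffer_mu(buf)
      for (k in seq_len(n)) {
        buf$tasksets[[k]]$contextual[cu] <-
          update_contextual(buf$tasksets[[k]]$contextual[cu], mu[k],
                            params$alpha_c)
      }
    }
  }
  list(response = resp, outcome = out, p_response = p_resp,
       p_correct = p_corr)
}

r_rl_engine <- function(tr, cue, protocol, params, predict_mode,
                        response, outcome, p_feedback) {
  n_s <- protocol$n_stimuli; n_a <- protocol$n_actions
  n_c <- max(protocol$n_cues, 1L)
  n_trials <- nrow(tr)
  q_sr <- matrix(1 / n_a, n_s, n_a)
  q_scr <- array(1 / n_a, dim = c(n_s, n_c, n_a))
  resp <- integer(n_trials); out <- integer(n_trials)
  p_resp <- numeric(n_trials); p_corr <- numeric(n_trials)
  omega <- params$omega

  for (t in seq_len(n_trials)) {
    s <- tr$stimulus[t]
    cu <- if (cue[t] > 0L) cue[t] else NA_integer_
    pol <- rl_policy(q_sr, s, params$beta, params$epsilon, omega,
                     if (omega > 0) q_scr else NULL, cu)
    if (predict_mode) {
      a <- response[t]; o <- outcome[t]
    } else {
      a <- draw_categorical(pol)
      p_pos <- if (a == tr$correct_response[t]) p_feedback else 1 - p_feedback
      o <- as.integer(stats::runif(1) < p_pos)
    }
    p_resp[t] <- pol[a]
    p_corr[t] <- pol[tr$correct_response[t]]
    resp[t] <- a; out[t] <- o
    q_sr[s, a] <- update_selective(q_sr[s, a], o, params$alpha_s)
    if (omega > 0 && !is.na(cu)) {
      q_scr[s, cu, a] <- update_selective(q_scr[s, cu, a], o, params$alpha_c)
    }
  }
  list(response = resp, outcome = out, p_response = p_resp,
       p_correct = p_corr)
}
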