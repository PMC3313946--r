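#' One-step-ahead log-likelihood of a behavioral log
#'
#' Evolves the model by conditioning on the log's actual responses and
#' outcomes and sums the log predicted probability of every observed
#' response. Probabilities are floored at 1e-12 so a surprising response
#' never yields an infinite penalty.
#'
#' @param params An `agent_params` object.
#' @param log A behavioral log.
#' @return The log-likelihood in nats (always `<= 0`).
#' @export
one_step_likelihood <- function(params, log) {
  pr <- predict_agent(params, log)$p_response
  sum(log(pmax(pr, 1e-12)))
}

#' Bayesian information criterion
#'
#' `BIC = -2 * LLH + n_params * log(n_trials)`; lower is better, penalizing
#' models with more free parameters.
#'
#' @param llh Maximized log-likelihood (nats).
#' @param n_params Number of free parameters.
#' @param n_trials Number of trials entering the likelihood.
#' @return The BIC value.
#' @export
bic <- function(llh, n_params, n_trials) {
  stopifnot(n_trials >= 1)
  -2 * llh + n_params * log(n_trials)
}

# least-squares objective: squared difference between observed correct
# frequencies and predicted correct-response probabilities per condition x
# trial-position curve
ls_objective <- function(params, log) {
  pc <- predict_agent(params, log)$p_correct
  obs <- as.integer(log$response == log$correct_response)
  pos <- log$trial_in_episode + 1L
  key <- interaction(log$condition, pos, drop = TRUE)
  obs_curve <- tapply(obs, key, mean)
  pred_curve <- tapply(pc, key, mean)
  sum((obs_curve - pred_curve)^2)
}

# free continuous parameters per model; integer capacity n is enumerated
# separately. Each row: name, transform ("log"/"logit"), start range.
model_param_spec <- function(model, cued) {
  spec <- switch(model,
    probe = data.frame(
      name = c("beta", "epsilon", "alpha_s", "eta", "theta"),
      transform = c("log", "logit", "logit", "logit", "logit"),
      lo = c(2, 0.005, 0.05, 0.1, 0.05), hi = c(60, 0.2, 0.9, 0.95, 0.95),
      stringsAsFactors = FALSE),
    max = data.frame(
      name = c("beta", "epsilon", "alpha_s", "eta"),
      transform = c("log", "logit", "logit", "logit"),
      lo = c(2, 0.005, 0.05, 0.1), hi = c(60, 0.2, 0.9, 0.95),
      stringsAsFactors = FALSE),
    forget = data.frame(
      name = c("beta", "epsilon", "alpha_s", "phi", "beta_actor"),
      transform = c("log", "logit", "logit", "logit", "log"),
      lo = c(2, 0.005, 0.05, 0.01, 1), hi = c(60, 0.2, 0.9, 0.5, 60),
      stringsAsFactors = FALSE),
    rl = data.frame(
      name = c("beta", "epsilon", "alpha_s"),
      transform = c("log", "logit", "logit"),
      lo = c(2, 0.005, 0.05), hi = c(60, 0.2, 0.9),
      stringsAsFactors = FALSE))
  if (cued) {
    extra <- if (model == "rl") {
      data.frame(name = c("omega", "alpha_c"),
                 transform = c("logit", "logit"),
                 lo = c(0.05, 0.005), hi = c(0.95, 0.3),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(name = c("alpha_c", "delta"),
                 transform = c("logit", "logit"),
                 lo = c(0.005, 0.05), hi = c(0.3, 0.9),
                 stringsAsFactors = FALSE)
    }
    spec <- rbind(spec, extra)
  }
  spec
}

to_unconstrained <- function(x, transform) {
  out <- numeric(length(x))
  is_log <- transform == "log"
  out[is_log] <- log(x[is_log])
  out[!is_log] <- stats::qlogis(x[!is_log])
  out
}
from_unconstrained <- function(z, transform) {
  z <- pmin(pmax(z, -30), 30)  # keep exp/plogis finite and parameters sane
  out <- numeric(length(z))
  is_log <- transform == "log"
  out[is_log] <- exp(z[is_log])
  out[!is_log] <- stats::plogis(z[!is_log])
  out
}

build_params <- function(model, values, n = NULL) {
  v <- as.list(values)
  common <- list(beta = v$beta, epsilon = v$epsilon, alpha_s = v$alpha_s)
  if (!is.null(v$alpha_c)) common$alpha_c <- v$alpha_c
  p <- switch(model,
    probe = do.call(probe_params, c(list(n = n, eta = v$eta, theta = v$theta,
      delta = if (is.null(v$delta)) 0 else v$delta), common)),
    max = do.call(max_params, c(list(n = n, eta = v$eta,
      delta = if (is.null(v$delta)) 0 else v$delta), common)),
    forget = do.call(forget_params, c(list(n = n, phi = v$phi,
      beta_actor = v$beta_actor,
      delta = if (is.null(v$delta)) 0 else v$delta), common)),
    rl = do.call(rl_params, c(list(omega = if (is.null(v$omega)) 0 else v$omega),
      common)))
  p
}

#' Fit a model to one participant's behavioral log
#'
#' Continuous parameters are optimized by multi-start Nelder-Mead on
#' log/logit-transformed coordinates; the integer monitoring capacity `N`
#' is enumerated exhaustively. The `"llh"` method maximizes the one-step-
#' ahead log-likelihood of the observed responses; the `"ls"` method
#' minimizes the squared difference between observed correct-response
#' frequencies and predicted correct-response probabilities per
#' condition-by-position curve.
#'
#' @param log A behavioral log covering at least one session.
#' @param model One of `"probe"`, `"max"`, `"forget"`, `"rl"`.
#' @param method `"llh"` or `"ls"`.
#' @param n_values Candidate capacities for the task-set models.
#' @param n_starts Nelder-Mead restarts per capacity value.
#' @param seed Seed for the optimizer starts (fitting is deterministic
#'   given data, seed and starts).
#' @param maxit Iteration cap per local search.
#' @return A `fit_result` list: `model`, `method`, `params` (fitted
#'   `agent_params`), `estimates` (named vector, including `n` where
#'   applicable), `llh`, `ls`, `bic`, `n_params`, `n_trials`, `converged`.
#' @export
fit_participant <- function(log, model = c("probe", "max", "forget", "rl"),
                            method = c("llh", "ls"), n_values = 1:6,
                            n_starts = 10L, seed = 1L, maxit = 300L) {
  model <- match.arg(model)
  method <- match.arg(method)
  cued <- !all(is.na(log$cue))
  spec <- model_param_spec(model, cued)
  n_trials <- nrow(log)
  if (model == "rl") n_values <- NA_integer_

  start_seeds <- split_seed(seed, n_starts)
  objective <- function(z, n) {
    vals <- stats::setNames(from_unconstrained(z, spec$transform), spec$name)
    p <- tryCatch(build_params(model, vals, n = n), error = function(e) NULL)
    if (is.null(p)) return(1e10)
    obj <- if (method == "llh") -one_step_likelihood(p, log)
           else ls_objective(p, log)
    if (!is.finite(obj)) 1e10 else obj
  }

  best <- NULL
  for (n in n_values) {
    for (st in seq_len(n_starts)) {
      set.seed(start_seeds[st])
      x0 <- stats::runif(nrow(spec), spec$lo, spec$hi)
      z0 <- to_unconstrained(x0, spec$transform)
      opt <- stats::optim(z0, objective, n = n, method = "Nelder-Mead",
                          control = list(maxit = maxit))
      if (is.null(best) || opt$value < best$value) {
        best <- list(value = opt$value, par = opt$par, n = n,
                     converged = opt$convergence == 0L)
      }
    }
  }

  vals <- stats::setNames(from_unconstrained(best$par, spec$transform),
                          spec$name)
  params <- build_params(model, vals,
                         n = if (is.na(best$n)) NULL else best$n)
  llh <- one_step_likelihood(params, log)
  ls <- ls_objective(params, log)
  n_params <- nrow(spec) + if (model == "rl") 0L else 1L  # + capacity N
  est <- vals
  if (!is.na(best$n)) est <- c(est, n = best$n)
  structure(list(model = model, method = method, params = params,
                 estimates = est, llh = llh, ls = ls,
                 bic = bic(llh, n_params, n_trials), n_params = n_params,
                 n_trials = n_trials, converged = best$converged),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("%s model fit (%s method): LLH = %.2f, LS = %.3f, BIC = %.1f\n",
              toupper(x$model), toupper(x$method), x$llh, x$ls, x$bic))
  cat("estimates:\n")
  print(round(x$estimates, 4))
  invisible(x)
}
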