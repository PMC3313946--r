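#' Create a task set
#'
#' A task set is one monitored behavioral strategy. It bundles a *selective*
#' mapping (expected reward value `Q[s, a]` of action `a` given stimulus `s`),
#' a *predictive* mapping (outcome likelihood `P(o | s, a)`, rows normalized
#' over outcomes), and a *contextual* mapping (reliability likelihood
#' `F(cue)` per contextual cue value), together with its current ex-ante
#' (`lam`) and ex-post (`mu`) reliability and LRU bookkeeping.
#'
#' @param id Integer label, stable for the lifetime of the set.
#' @param n_stimuli,n_actions,n_outcomes,n_cues Dimensions of the mappings.
#'   `n_cues = 0` means the protocol carries no contextual cues.
#' @param selective Optional `n_stimuli x n_actions` matrix of Q values;
#'   defaults to the uninformative value `1/n_actions` everywhere.
#' @param predictive Optional `n_stimuli x n_actions x n_outcomes` array of
#'   outcome likelihoods; defaults to uniform rows.
#' @param contextual Optional numeric vector of length `n_cues`; defaults to
#'   the neutral baseline `1/n_cues`.
#' @param lam,mu Initial reliabilities in `[0, 1]`.
#' @param last_actor_trial Trial index at which the set last acted (for LRU
#'   eviction); `0` for a set that never acted.
#'
#' @return An object of class `task_set`.
#' @export
task_set <- function(id, n_stimuli = 3L, n_actions = 4L, n_outcomes = 2L,
                     n_cues = 0L, selective = NULL, predictive = NULL,
                     contextual = NULL, lam = 0, mu = 0,
                     last_actor_trial = 0L) {
  if (is.null(selective)) {
    selective <- matrix(1 / n_actions, n_stimuli, n_actions)
  }
  if (is.null(predictive)) {
    predictive <- array(1 / n_outcomes, dim = c(n_stimuli, n_actions, n_outcomes))
  }
  if (is.null(contextual)) {
    contextual <- if (n_cues > 0L) rep(1 / n_cues, n_cues) else numeric(0)
  }
  ts <- structure(
    list(id = as.integer(id), selective = selective, predictive = predictive,
         contextual = contextual,
         pred_weight = matrix(1, n_stimuli, n_actions),
         lam = lam, mu = mu,
         last_actor_trial = as.integer(last_actor_trial)),
    class = "task_set")
  validate_task_set(ts)
  ts
}

validate_task_set <- function(ts) {
  stopifnot(is.matrix(ts$selective), is.array(ts$predictive))
  sums <- apply(ts$predictive, c(1, 2), sum)
  if (any(abs(sums - 1) > 1e-8)) {
    stop("predictive rows must sum to 1 over outcomes", call. = FALSE)
  }
  if (ts$lam < 0 || ts$lam > 1 || ts$mu < 0 || ts$mu > 1) {
    stop("reliabilities must lie in [0, 1]", call. = FALSE)
  }
  if (length(ts$contextual) && (min(ts$contextual) < 0 || max(ts$contextual) > 1)) {
    stop("contextual values must lie in [0, 1]", call. = FALSE)
  }
  invisible(ts)
}

#' Create a monitoring buffer
#'
#' The monitoring buffer holds the task sets whose reliability is tracked
#' concurrently (at most `capacity`, plus one transient unconfirmed probe),
#' together with the null-hypothesis mass: `lam0`/`mu0` are the ex-ante and
#' ex-post probabilities that *no* monitored task set matches the current
#' hidden external state. With an empty history all hypotheses are presumed
#' equally reliable, so an empty buffer starts with all mass on the null.
#'
#' @param capacity Monitoring capacity `N >= 1`.
#' @param tasksets List of [task_set] objects (possibly empty).
#' @param lam0,mu0 Null-hypothesis reliabilities. Defaults put all remaining
#'   mass (1 minus the sets' reliabilities) on the null.
#' @param probe_id Id of the current unconfirmed probe set, or `NA`.
#' @param actor_id Id of the current actor set, or `NA`.
#'
#' @return An object of class `monitoring_buffer`.
#' @export
monitoring_buffer <- function(capacity, tasksets = list(), lam0 = NULL,
                              mu0 = NULL, probe_id = NA_integer_,
                              actor_id = NA_integer_) {
  stopifnot(capacity >= 1)
  if (is.null(lam0)) lam0 <- 1 - sum(vapply(tasksets, `[[`, 0, "lam"))
  if (is.null(mu0)) mu0 <- 1 - sum(vapply(tasksets, `[[`, 0, "mu"))
  buf <- structure(
    list(tasksets = tasksets, capacity = as.integer(capacity),
         lam0 = lam0, mu0 = mu0, probe_id = as.integer(probe_id),
         actor_id = as.integer(actor_id)),
    class = "monitoring_buffer")
  validate_buffer(buf)
  buf
}

validate_buffer <- function(buf) {
  n_t <- length(buf$tasksets)
  if (n_t > buf$capacity + 1L) {
    stop("buffer may hold at most capacity + 1 task sets (transient probe)",
         call. = FALSE)
  }
  lam <- buffer_lam(buf)
  mu <- buffer_mu(buf)
  if (n_t > 0 || buf$lam0 > 0) {
    if (abs(buf$lam0 + sum(lam) - 1) > 1e-8 || abs(buf$mu0 + sum(mu) - 1) > 1e-8) {
      stop("reliabilities must be normalized including the null mass",
           call. = FALSE)
    }
  }
  if (sum(lam > 0.5) > 1L) {
    stop("at most one task set can have lam > 0.5", call. = FALSE)
  }
  invisible(buf)
}

#' @rdname monitoring_buffer
#' @param buf A `monitoring_buffer`.
#' @return `buffer_lam()` / `buffer_mu()` return the vector of task-set
#'   ex-ante / ex-post reliabilities (excluding the null mass);
#'   `buffer_ids()` the integer ids.
#' @export
buffer_lam <- function(buf) vapply(buf$tasksets, `[[`, 0, "lam")

#' @rdname monitoring_buffer
#' @export
buffer_mu <- function(buf) vapply(buf$tasksets, `[[`, 0, "mu")

#' @rdname monitoring_buffer
#' @export
buffer_ids <- function(buf) vapply(buf$tasksets, `[[`, 0L, "id")

buffer_index <- function(buf, id) {
  ix <- match(id, buffer_ids(buf))
  if (is.na(ix)) stop("no task set with id ", id, " in buffer", call. = FALSE)
  ix
}

#' Create an empty long-term memory store
#'
#' Long-term memory is an append-only store of behavioral strategies: the
#' selective and predictive mappings of every confirmed task set, plus a
#' snapshot of its contextual mapping. Entries are never removed; eviction
#' from the monitoring buffer only refreshes the stored mappings so that the
#' strategy can later be recollected through [create_probe()].
#'
#' @return An object of class `long_term_memory`.
#' @export
long_term_memory <- function() {
  structure(list(strategies = list(), ids = integer(0)),
            class = "long_term_memory")
}

#' Store or refresh a strategy in long-term memory
#'
#' @param ltm A [long_term_memory] object.
#' @param ts A [task_set] whose mappings are to be stored.
#' @return The updated store. Storing an id already present refreshes the
#'   entry in place (the store never shrinks).
#' @export
ltm_store <- function(ltm, ts) {
  entry <- list(id = ts$id, selective = ts$selective,
                predictive = ts$predictive, contextual = ts$contextual)
  ix <- match(ts$id, ltm$ids)
  if (is.na(ix)) {
    ltm$strategies[[length(ltm$strategies) + 1L]] <- entry
    ltm$ids <- c(ltm$ids, ts$id)
  } else {
    ltm$strategies[[ix]] <- entry
  }
  ltm
}

#' @rdname ltm_store
#' @export
ltm_size <- function(ltm) length(ltm$strategies)
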