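#' Classify responses as correct, perseverative or exploratory
#'
#' Correct responses are the best responses of the ongoing episode;
#' perseverative responses are the best responses of the *preceding*
#' episode for the same stimulus (and not correct now); exploratory
#' responses are neither. In the first episode of a session no preceding
#' mapping exists, so non-correct responses there are unclassifiable and
#' labelled `NA`.
#'
#' @param log A behavioral log (see [simulate_agent()]).
#' @return A character vector of labels (`"correct"`, `"perseverative"`,
#'   `"exploratory"`, or `NA`), one per trial.
#' @export
classify_responses <- function(log) {
  labels <- rep(NA_character_, nrow(log))
  key_cols <- intersect(c("session_id", "seed", "agent"), names(log))
  key <- interaction(log[key_cols], drop = TRUE)
  for (sid in levels(key)) {
    rows <- which(key == sid)
    sl <- log[rows, ]
    n_s <- max(sl$stimulus)
    prev_map <- rep(NA_integer_, n_s)
    for (e in sort(unique(sl$episode_index))) {
      ix <- which(sl$episode_index == e)
      cur_map <- rep(NA_integer_, n_s)
      cur_map[sl$stimulus[ix]] <- sl$correct_response[ix]
      for (i in ix) {
        if (sl$response[i] == sl$correct_response[i]) {
          labels[rows[i]] <- "correct"
        } else if (!is.na(prev_map[sl$stimulus[i]])) {
          labels[rows[i]] <-
            if (sl$response[i] == prev_map[sl$stimulus[i]]) "perseverative"
            else "exploratory"
        }
      }
      prev_map <- cur_map
    }
  }
  labels
}

# one factor level per (run, session, episode); runs are told apart by the
# seed and agent columns when present
episode_key <- function(log) {
  key_cols <- intersect(c("session_id", "seed", "agent", "episode_index"),
                        names(log))
  interaction(log[key_cols], drop = TRUE)
}

# 0/1 perseverative flag used in the log schema; NA where undefined
perseverative_flags <- function(log) {
  lab <- classify_responses(log)
  out <- as.integer(lab == "perseverative")
  out[is.na(lab)] <- NA_integer_
  out
}

#' Episode-aligned response rates
#'
#' Mean correct, perseverative and exploratory response rates per trial
#' position since episode onset (position 1 = first trial of an episode),
#' averaged over episodes within each condition, with the standard error of
#' the mean across episodes.
#'
#' @param log A behavioral log (may pool several runs; every
#'   `(session_id, seed, episode_index)` combination counts as one episode).
#' @param max_trial Largest position reported.
#' @return A `data.frame` with columns `condition`, `trial`, `n_episodes`,
#'   `rate_correct`, `rate_perseverative`, `rate_exploratory`,
#'   `sem_correct`.
#' @export
aligned_rates <- function(log, max_trial = 30L) {
  lab <- classify_responses(log)
  pos <- log$trial_in_episode + 1L
  ep_key <- episode_key(log)
  keep <- pos <= max_trial
  d <- data.frame(condition = log$condition[keep], pos = pos[keep],
                  ep = ep_key[keep],
                  correct = as.integer(log$response == log$correct_response)[keep],
                  persev = as.integer(lab[keep] == "perseverative"),
                  explor = as.integer(lab[keep] == "exploratory"))
  out <- do.call(rbind, lapply(split(d, list(d$condition, d$pos), drop = TRUE),
    function(g) {
      ep_means <- tapply(g$correct, g$ep, mean)
      ep_means <- ep_means[!is.na(ep_means)]
      data.frame(
        condition = g$condition[1L], trial = g$pos[1L],
        n_episodes = length(ep_means),
        rate_correct = mean(g$correct),
        rate_perseverative = mean(g$persev, na.rm = TRUE),
        rate_exploratory = mean(g$explor, na.rm = TRUE),
        sem_correct = stats::sd(ep_means) / sqrt(max(length(ep_means), 1L)),
        stringsAsFactors = FALSE)
    }))
  out <- out[order(out$condition, out$trial), ]
  rownames(out) <- NULL
  out
}

#' Plug-in mutual information of a 2x2 pair table
#'
#' @param counts Length-4 vector or 2x2 matrix of pair counts, ordered
#'   `(0,0), (0,1), (1,0), (1,1)` when a vector.
#' @return Mutual information in bits (non-negative; invariant under
#'   relabeling 0 and 1).
#' @export
pair_mutual_information <- function(counts) {
  m <- matrix(as.numeric(counts), 2L, 2L, byrow = TRUE)
  n <- sum(m)
  if (n <= 0) return(NA_real_)
  p <- m / n
  pr <- rowSums(p); pc <- colSums(p)
  mi <- 0
  for (i in 1:2) for (j in 1:2) {
    if (p[i, j] > 0) mi <- mi + p[i, j] * log2(p[i, j] / (pr[i] * pc[j]))
  }
  max(mi, 0)
}

#' Mutual dependence of successive correct decisions
#'
#' For each condition and each five-trial sliding window over positions
#' since episode onset, pools the pairs of successive correctness
#' indicators `(c_t, c_(t+1))` over episodes (pairs never straddle episode
#' boundaries) and reports their plug-in mutual information in bits. A
#' strong early peak indicates that a single feedback drives retrieval of a
#' whole stimulus-response mapping rather than of individual associations.
#'
#' @param log A behavioral log.
#' @param bin_width Window width in trials (default 5).
#' @param max_trial Largest window start position.
#' @return A `data.frame` with `condition`, `trial` (window start),
#'   `mi_bits`, `n_pairs` (`mi_bits` is `NA` for windows with fewer than 2
#'   pairs).
#' @export
mutual_dependence <- function(log, bin_width = 5L, max_trial = 30L) {
  pos <- log$trial_in_episode + 1L
  ep_key <- episode_key(log)
  correct <- as.integer(log$response == log$correct_response)
  # successive pairs within episodes
  n <- nrow(log)
  same_ep <- ep_key[-n] == ep_key[-1L]
  pair_pos <- pos[-n][same_ep]
  c1 <- correct[-n][same_ep]
  c2 <- correct[-1L][same_ep]
  out <- list()
  for (cond in unique(log$condition)) {
    in_cond <- log$condition[-n][same_ep] == cond
    for (w in seq_len(max_trial)) {
      sel <- in_cond & pair_pos >= w & pair_pos < w + bin_width
      np <- sum(sel)
      mi <- if (np < 2L) NA_real_ else {
        pair_mutual_information(c(
          sum(c1[sel] == 0 & c2[sel] == 0), sum(c1[sel] == 0 & c2[sel] == 1),
          sum(c1[sel] == 1 & c2[sel] == 0), sum(c1[sel] == 1 & c2[sel] == 1)))
      }
      out[[length(out) + 1L]] <- data.frame(
        condition = cond, trial = w, mi_bits = mi, n_pairs = np,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Derive reproducible child seeds from one master seed
#'
#' A single run seed expands into independent component seeds (protocol
#' generation, agent simulation, optimizer starts) by seeding R's RNG with
#' the master seed and drawing integers below 2^31.
#'
#' @param seed Master integer seed.
#' @param n Number of child seeds.
#' @return An integer vector of length `n`.
#' @export
split_seed <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(seed)
  out <- sample.int(2147483646L, n)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  out
}

#' Simulate a full uncued two-session experiment
#'
#' One open and one recurrent session (25 episodes each, lengths 36-54,
#' 90/10 feedback), fresh protocols and a fresh agent per call.
#'
#' @param params An `agent_params` object.
#' @param seed Integer seed (expanded into protocol and agent child seeds).
#' @return The pooled behavioral log of both sessions.
#' @export
simulate_exp1 <- function(params, seed) {
  s <- split_seed(seed, 4L)
  open <- generate_open_session(s[1L])
  rec <- generate_recurrent_session(s[2L])
  rbind(simulate_agent(params, open, seed = s[3L]),
        simulate_agent(params, rec, seed = s[4L]))
}

#' Optimize model performance over a parameter grid
#'
#' Evaluates the mean proportion of correct responses produced by the model
#' over simulated experiments for every combination of the supplied
#' parameter values, and returns the argmax. Replicate seeds are shared
#' across grid points (common random numbers), so grid comparisons are
#' paired.
#'
#' @param base_params An `agent_params` object supplying the fixed
#'   parameters.
#' @param grid Named list of parameter value vectors to cross.
#' @param n_reps Simulated experiments per grid point.
#' @param seed Master seed.
#' @param simulate_fn Function `(params, seed) -> log` defining the
#'   protocol family (default [simulate_exp1()]).
#' @return A list with `best` (named list of the best parameter values),
#'   `best_rate`, and `surface` (a `data.frame` of grid values and mean
#'   correct rates).
#' @export
optimize_performance <- function(base_params, grid, n_reps = 50L, seed = 1L,
                                 simulate_fn = simulate_exp1) {
  stopifnot(length(grid) >= 1L, !is.null(names(grid)))
  gd <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  rep_seeds <- split_seed(seed, n_reps)
  rates <- numeric(nrow(gd))
  for (i in seq_len(nrow(gd))) {
    p <- base_params
    for (nm in names(gd)) p[[nm]] <- gd[[nm]][i]
    if (!is.null(p$n)) p$n <- as.integer(p$n)
    if (!is.null(p$alpha_p) && "alpha_s" %in% names(gd)) p$alpha_p <- p$alpha_s
    rates[i] <- mean(vapply(rep_seeds, function(rs) {
      mean(simulate_fn(p, rs)$is_correct)
    }, 0))
  }
  surface <- cbind(gd, mean_correct = rates)
  best_ix <- which.max(rates)
  list(best = as.list(gd[best_ix, , drop = FALSE]),
       best_rate = rates[best_ix], surface = surface)
}
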