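#' Enumerate injective stimulus-response mappings
#'
#' Lists every assignment of distinct responses to the stimuli. With 3
#' stimuli and 4 responses there are `4!/1! = 24` mappings, and each fixed
#' stimulus-response association belongs to exactly 6 of them.
#'
#' @param n_stimuli Number of stimuli.
#' @param n_responses Number of responses (`>= n_stimuli`).
#' @return An integer matrix with one mapping per row; entry `[m, s]` is the
#'   correct response to stimulus `s` under mapping `m`.
#' @export
enumerate_mappings <- function(n_stimuli = 3L, n_responses = 4L) {
  if (n_responses < n_stimuli) {
    stop("injective mappings need at least as many responses as stimuli",
         call. = FALSE)
  }
  grid <- as.matrix(expand.grid(rep(list(seq_len(n_responses)), n_stimuli)))
  keep <- apply(grid, 1L, function(x) !anyDuplicated(x))
  m <- grid[keep, , drop = FALSE]
  dimnames(m) <- NULL
  m[do.call(order, as.data.frame(m)), , drop = FALSE]
}

#' Number of shared stimulus-response associations between two mappings
#' @param m1,m2 Integer mapping vectors (response per stimulus).
#' @return Count of stimuli mapped to the same response.
#' @export
mapping_overlap <- function(m1, m2) sum(m1 == m2)

# Fully incongruent mapping family: rows of a randomized 4x4 Latin square
# restricted to the stimulus columns are pairwise disjoint injections.
incongruent_mappings <- function(n_mappings, n_stimuli = 3L, n_responses = 4L) {
  stopifnot(n_mappings <= n_responses)
  base <- outer(seq_len(n_responses), seq_len(n_responses) - 1L, `+`)
  base <- (base - 1L) %% n_responses + 1L
  relab <- sample.int(n_responses)
  sq <- matrix(relab[base], n_responses, n_responses)
  sq <- sq[sample.int(n_responses), sample.int(n_responses), drop = FALSE]
  sq[seq_len(n_mappings), seq_len(n_stimuli), drop = FALSE]
}

# Random order of all 24 mappings such that consecutive mappings (and the
# wrap-around back to the first) share no association. The non-overlap graph
# is dense (degree 11 of 23), so a randomized greedy walk with restarts
# terminates quickly.
order_nonoverlapping <- function(mappings, max_tries = 5000L) {
  n <- nrow(mappings)
  adj <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j) {
    i != j && mapping_overlap(mappings[i, ], mappings[j, ]) == 0L
  }))
  for (try in seq_len(max_tries)) {
    path <- sample.int(n, 1L)
    used <- logical(n)
    used[path] <- TRUE
    repeat {
      nb <- which(adj[path[length(path)], ] & !used)
      if (!length(nb)) break
      nxt <- if (length(nb) == 1L) nb else sample(nb, 1L)
      path <- c(path, nxt)
      used[nxt] <- TRUE
    }
    if (length(path) == n && adj[path[n], path[1L]]) return(path)
  }
  stop("failed to order mappings without successive overlap", call. = FALSE)
}

# Random Eulerian circuit on the complete directed multigraph over
# `n_nodes` with `per_pair` copies of each ordered pair. Yields an episode
# sequence with exactly equalized transition counts and no immediate
# repeats; node visit counts differ by one only for the starting node.
eulerian_sequence <- function(n_nodes, per_pair) {
  remaining <- matrix(per_pair, n_nodes, n_nodes)
  diag(remaining) <- 0L
  start <- sample.int(n_nodes, 1L)
  # Hierholzer with random edge choice
  circuit <- integer(0)
  stack <- start
  while (length(stack)) {
    v <- stack[length(stack)]
    nb <- which(remaining[v, ] > 0L)
    if (length(nb)) {
      w <- if (length(nb) == 1L) nb else sample(nb, 1L)
      remaining[v, w] <- remaining[v, w] - 1L
      stack <- c(stack, w)
    } else {
      circuit <- c(v, circuit)
      stack <- stack[-length(stack)]
    }
  }
  circuit
}

# Balanced pseudo-random stimulus sequence: shuffled blocks over the
# stimulus set, truncated to the episode length.
stimulus_sequence <- function(len, n_stimuli) {
  blocks <- ceiling(len / n_stimuli)
  seq <- unlist(lapply(seq_len(blocks), function(i) sample.int(n_stimuli)))
  seq[seq_len(len)]
}

episode_lengths <- function(n_episodes, min_len = 36L, max_len = 54L) {
  sample(seq(min_len, max_len), n_episodes, replace = TRUE)
}

# Assemble the trial-level schedule from episode-level structure.
build_protocol <- function(experiment, session_id, mappings, mapping_seq,
                           lengths, conditions, cue_seq = NULL, n_cues = 0L,
                           seed = NA_integer_, n_stimuli = 3L, n_actions = 4L) {
  n_ep <- length(mapping_seq)
  trials <- vector("list", n_ep)
  for (e in seq_len(n_ep)) {
    len <- lengths[e]
    stim <- stimulus_sequence(len, n_stimuli)
    cues <- if (is.null(cue_seq)) rep(NA_integer_, len) else cue_seq[[e]]
    trials[[e]] <- data.frame(
      episode_index = e,
      trial_in_episode = seq_len(len) - 1L,
      stimulus = stim,
      cue = cues,
      correct_response = mappings[mapping_seq[e], stim],
      condition = conditions[e],
      stringsAsFactors = FALSE)
  }
  structure(list(
    experiment = experiment,
    session_id = session_id,
    n_stimuli = as.integer(n_stimuli),
    n_actions = as.integer(n_actions),
    n_cues = as.integer(n_cues),
    seed = seed,
    mappings = mappings,
    episodes = data.frame(episode = seq_len(n_ep), mapping = mapping_seq,
                          length = lengths, condition = conditions,
                          stringsAsFactors = FALSE),
    trials = do.call(rbind, trials)),
    class = "session_protocol")
}

#' Generate an open session
#'
#' 25 episodes of 36-54 trials. Episodes 1-24 use each of the 24 injective
#' mappings exactly once, ordered so that two successive mappings share no
#' stimulus-response association; episode 25 reuses the first episode's
#' mapping (the 24-25 transition is also overlap-free, since the ordering is
#' cyclic).
#'
#' @param seed Integer seed; the schedule is reproducible from it.
#' @return A `session_protocol`.
#' @export
generate_open_session <- function(seed) {
  set.seed(seed)
  mappings <- enumerate_mappings(3L, 4L)
  ord <- order_nonoverlapping(mappings)
  mapping_seq <- c(ord, ord[1L])
  build_protocol("exp1_open", "open", mappings, mapping_seq,
                 episode_lengths(25L), rep("open", 25L), seed = seed)
}

#' Generate a recurrent session
#'
#' With three mappings: 25 episodes in which three mutually non-overlapping
#' mappings reoccur pseudo-randomly with repetition counts 8/8/9, exactly
#' equalized transition frequencies, and no immediate repeats (the episode
#' sequence is a random Eulerian circuit over the mapping-transition
#' multigraph). With four mappings: 24 episodes over four fully incongruent
#' mappings, balanced counts, no immediate repeats.
#'
#' @param seed Integer seed.
#' @param n_mappings 3 (default) or 4 reoccurring mappings.
#' @return A `session_protocol`.
#' @export
generate_recurrent_session <- function(seed, n_mappings = 3L) {
  stopifnot(n_mappings %in% c(3L, 4L))
  set.seed(seed)
  mappings <- incongruent_mappings(n_mappings)
  if (n_mappings == 3L) {
    mapping_seq <- eulerian_sequence(3L, 4L)  # 25 episodes, counts 9/8/8
    experiment <- "exp1_recurrent"
  } else {
    repeat {
      mapping_seq <- sample(rep(seq_len(4L), 6L))
      if (all(diff(mapping_seq) != 0L)) break
    }
    experiment <- "recurrent4"
  }
  n_ep <- length(mapping_seq)
  build_protocol(experiment, "recurrent", mappings, mapping_seq,
                 episode_lengths(n_ep), rep("recurrent", n_ep), seed = seed)
}

# Cue sequence for one episode: constant cue, or (for dual-cue mappings)
# at most one within-episode switch between the mapping's two cues.
episode_cues <- function(len, cues, allow_switch = TRUE) {
  if (length(cues) == 1L) return(rep(cues, len))
  first <- sample(cues, 1L)
  if (!allow_switch || stats::runif(1) > 0.5) return(rep(first, len))
  cut <- sample(seq(floor(len / 3), ceiling(2 * len / 3)), 1L)
  c(rep(first, cut), rep(setdiff(cues, first), len - cut))
}

#' Generate the color-cued sessions
#'
#' Session 1 is a three-mapping recurrent session in which stimulus colors
#' predict the mapping with 100% reliability: two mappings carry one unique
#' cue each, the third carries two possible cues (so that cues can change at
#' most once within such episodes without an episode change). Session 2
#' starts with 13 rehearsal episodes identical in structure to session 1,
#' followed by 12 intermixed test episodes: 4 *control* episodes (the
#' dual-cue recurrent mapping with its learned cues), 6 *transfer* episodes
#' (the two other recurrent mappings, now with novel cues), and 2 *open*
#' episodes (a novel mapping, fully incongruent with the recurrent three,
#' with novel cues).
#'
#' @param seed Integer seed.
#' @return A list with `session1` and `session2`, both `session_protocol`s
#'   sharing the mapping set and an 8-value cue alphabet.
#' @export
generate_cued_sessions <- function(seed) {
  set.seed(seed)
  mappings <- incongruent_mappings(4L)  # rows 1-3 recurrent, row 4 open
  cue_of <- list(`1` = 1L, `2` = 2L, `3` = c(3L, 4L))
  n_cues <- 8L

  recurrent_cued <- function(session_id, mapping_seq, conditions, experiment) {
    lengths <- episode_lengths(length(mapping_seq))
    cue_seq <- lapply(seq_along(mapping_seq), function(e) {
      episode_cues(lengths[e], cue_of[[as.character(mapping_seq[e])]])
    })
    build_protocol(experiment, session_id, mappings, mapping_seq, lengths,
                   conditions, cue_seq, n_cues = n_cues, seed = seed)
  }

  session1 <- recurrent_cued("cued_recurrent", eulerian_sequence(3L, 4L),
                             rep("recurrent", 25L), "exp2_session1")

  # session 2: 13 rehearsal episodes (counts 4/4/5, no immediate repeats)
  repeat {
    rehearsal_seq <- sample(rep(seq_len(3L), c(4L, 4L, 5L)))
    if (all(diff(rehearsal_seq) != 0L)) break
  }
  # test block: mapping / condition / cues per episode
  test <- list(
    list(m = 3L, cond = "control", cues = c(3L, 4L)),
    list(m = 3L, cond = "control", cues = c(3L, 4L)),
    list(m = 3L, cond = "control", cues = c(3L, 4L)),
    list(m = 3L, cond = "control", cues = c(3L, 4L)),
    list(m = 1L, cond = "transfer", cues = 5L),
    list(m = 1L, cond = "transfer", cues = 5L),
    list(m = 1L, cond = "transfer", cues = 5L),
    list(m = 2L, cond = "transfer", cues = 6L),
    list(m = 2L, cond = "transfer", cues = 6L),
    list(m = 2L, cond = "transfer", cues = 6L),
    list(m = 4L, cond = "open", cues = 7L),
    list(m = 4L, cond = "open", cues = 8L))
  repeat {
    test_ord <- sample(seq_along(test))
    ms <- vapply(test[test_ord], `[[`, 0L, "m")
    if (all(diff(ms) != 0L) && ms[1L] != rehearsal_seq[length(rehearsal_seq)]) break
  }
  test <- test[test_ord]
  mapping_seq <- c(rehearsal_seq, vapply(test, `[[`, 0L, "m"))
  conditions <- c(rep("rehearsal", 13L), vapply(test, `[[`, "", "cond"))
  lengths <- episode_lengths(25L)
  cue_seq <- vector("list", 25L)
  for (e in 1:13) {
    cue_seq[[e]] <- episode_cues(lengths[e],
                                 cue_of[[as.character(rehearsal_seq[e])]])
  }
  for (e in 14:25) {
    cue_seq[[e]] <- episode_cues(lengths[e], test[[e - 13L]]$cues)
  }
  session2 <- build_protocol("exp2_session2", "cued_test", mappings,
                             mapping_seq, lengths, conditions, cue_seq,
                             n_cues = n_cues, seed = seed)
  list(session1 = session1, session2 = session2)
}

#' Sample probabilistic feedback for one trial
#'
#' The correct action yields positive feedback with probability
#' `p_correct`; every other action with probability `1 - p_correct`
#' (defaults 0.9 / 0.1).
#'
#' @param mapping Integer mapping vector (correct response per stimulus).
#' @param s,a 1-based stimulus and action.
#' @param p_correct Positive-feedback probability for the correct action.
#' @return 1 for positive feedback, 0 for negative.
#' @export
sample_feedback <- function(mapping, s, a, p_correct = 0.9) {
  p <- if (a == mapping[s]) p_correct else 1 - p_correct
  as.integer(stats::runif(1) < p)
}

#' Write / read a protocol as JSON
#'
#' @param protocol A `session_protocol`.
#' @param path File path.
#' @return `read_protocol()` returns the `session_protocol`.
#' @export
write_protocol <- function(protocol, path) {
  jsonlite::write_json(unclass(protocol), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$mappings <- matrix(as.integer(x$mappings), nrow = nrow(x$mappings))
  x$episodes <- as.data.frame(x$episodes, stringsAsFactors = FALSE)
  x$trials <- as.data.frame(x$trials, stringsAsFactors = FALSE)
  x$trials$cue <- as.integer(x$trials$cue)
  structure(x, class = "session_protocol")
}
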