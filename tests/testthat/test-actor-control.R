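flat <- function() matrix(0.5, 3, 4)

test_that("actor selection is satisficing on the 0.5 criterion", {
  buf <- monitoring_buffer(3, list(make_ts(1, flat(), lam = 0.7),
                                   make_ts(2, flat(), lam = 0.2)),
                           lam0 = 0.1)
  expect_equal(select_actor(buf), list(action = "actor", actor_id = 1L))

  buf2 <- monitoring_buffer(3, list(make_ts(1, flat(), lam = 0.33),
                                    make_ts(2, flat(), lam = 0.33)),
                            lam0 = 0.34)
  expect_equal(select_actor(buf2)$action, "create")

  # binary control: with two monitored sets and a vanishing null,
  # de-selection of the actor implies selection of the other set
  buf3 <- monitoring_buffer(3, list(make_ts(1, flat(), lam = 0.3),
                                    make_ts(2, flat(), lam = 0.699)),
                            lam0 = 0.001)
  expect_equal(select_actor(buf3), list(action = "actor", actor_id = 2L))

  # an unresolved probe stays in charge when nobody is reliable
  buf4 <- monitoring_buffer(3, list(make_ts(1, flat(), lam = 0.3),
                                    make_ts(9, flat(), lam = 0.2)),
                            lam0 = 0.5, probe_id = 9L)
  expect_equal(select_actor(buf4),
               list(action = "continue_probe", actor_id = 9L))
})

test_that("binary-control property holds for random two-set configurations", {
  set.seed(11)
  for (i in 1:50) {
    lam_actor <- runif(1, 0.01, 0.499)
    lam0 <- runif(1, 0, 1e-4)
    buf <- monitoring_buffer(
      2, list(make_ts(1, flat(), lam = lam_actor),
              make_ts(2, flat(), lam = 1 - lam0 - lam_actor)),
      lam0 = lam0)
    sel <- select_actor(buf)
    expect_equal(sel$action, "actor")
    expect_equal(sel$actor_id, 2L)
  }
})

test_that("probe creation mixes long-term memory with the random strategy", {
  ltm <- long_term_memory()
  # full-noise limit: the random strategy regardless of memory
  q1 <- matrix(runif(12), 3, 4)
  ltm <- ltm_store(ltm, make_ts(1, flat()))
  probe <- create_probe(ltm, 99, eta = 1)
  expect_equal(probe$selective, matrix(0.25, 3, 4))
  expect_equal(probe$predictive[1, 1, ], baseline_predictive(4))

  # noiseless single-source recollection is an exact copy
  ts1 <- make_ts(5, matrix(0.8, 3, 4))
  ts1$selective <- q1
  ltm2 <- ltm_store(long_term_memory(), ts1)
  probe2 <- create_probe(ltm2, 100, eta = 0)
  expect_equal(probe2$selective, q1)
  expect_equal(probe2$predictive, ts1$predictive)

  # two equally weighted strategies with Q values 1 and 0 at eta = 0.5:
  # M = 0.5 * 0.5 * (1 + 0) + 0.5 * U
  tsA <- make_ts(1, flat()); tsA$selective[, ] <- 1
  tsB <- make_ts(2, flat()); tsB$selective[, ] <- 0
  ltm3 <- ltm_store(ltm_store(long_term_memory(), tsA), tsB)
  probe3 <- create_probe(ltm3, 101, eta = 0.5)
  expect_equal(probe3$selective[1, 1], 0.5 * 0.5 * 1 + 0.5 * 0.25)

  # cold start: empty memory gives the pure random strategy
  probe4 <- create_probe(long_term_memory(), 102, eta = 0.3)
  expect_equal(probe4$selective, matrix(0.25, 3, 4))
})

test_that("cue-weighted recollection favors the cued strategy", {
  tsA <- make_ts(1, matrix(0.9, 3, 4), n_cues = 2L, contextual = c(1, 0))
  tsA$selective[, ] <- 1
  tsB <- make_ts(2, matrix(0.9, 3, 4), n_cues = 2L, contextual = c(0, 1))
  tsB$selective[, ] <- 0
  ltm <- ltm_store(ltm_store(long_term_memory(), tsA), tsB)
  probe <- create_probe(ltm, 3, eta = 0, cue = 1L, n_cues = 2L)
  expect_equal(probe$selective, tsA$selective)
})

test_that("maximum-entropy prior reproduces the printed bounds", {
  # single monitored set (the probe itself): upper bound 1/3
  expect_equal(prior_reliability(numeric(0)), 1 / 3)
  expect_equal(prior_reliability(0.8), 1 / 3)
  # two equally reliable non-actor sets: lower bound 1/(N_t + 1) = 1/4
  expect_equal(prior_reliability(c(0.3, 0.3)), 0.25)
  # randomized configurations stay in [1/(N_t+1), 1/3] and below 0.5
  set.seed(3)
  for (i in 1:200) {
    n_t <- sample(1:5, 1)          # including the probe
    lam <- runif(n_t - 1, 0, 0.5)
    lp <- prior_reliability(lam)
    if (n_t >= 2) expect_gte(lp, 1 / (n_t + 1) - 1e-12)
    expect_lte(lp, 1 / 3 + 1e-12)
    expect_lte(apply_confirmation_bias(lp, runif(1)), 0.5)
  }
})

test_that("confirmation bias pulls the prior toward the 0.5 threshold", {
  expect_equal(apply_confirmation_bias(1 / 3, 0), 1 / 3)
  expect_equal(apply_confirmation_bias(1 / 3, 1), 0.5)
  expect_equal(apply_confirmation_bias(1 / 3, 0.74), 0.4566667,
               tolerance = 1e-6)
})

test_that("probe resolution follows the hypothesis-testing rules", {
  mk <- function(lam_probe, lam_other) {
    monitoring_buffer(3, list(make_ts(1, flat(), lam = lam_other),
                              make_ts(2, flat(), lam = lam_probe)),
                      lam0 = 1 - lam_probe - lam_other, probe_id = 2L)
  }
  expect_equal(resolve_probe(mk(0.6, 0.2)), "confirm")
  expect_equal(resolve_probe(mk(0.2, 0.7)), "discard")
  expect_equal(resolve_probe(mk(0.4, 0.45)), "continue")
  expect_error(resolve_probe(monitoring_buffer(2)), "no active probe")
})

test_that("probe installation rescales the remaining hypotheses", {
  buf <- monitoring_buffer(3, list(make_ts(1, flat(), lam = 0.4, mu = 0.4)))
  probe <- create_probe(long_term_memory(), 2, eta = 1)
  b <- install_probe(buf, probe, theta = 0)
  expect_equal(b$probe_id, 2L)
  expect_equal(b$actor_id, 2L)
  expect_equal(b$lam0 + sum(buffer_lam(b)), 1, tolerance = 1e-12)
  # prior over one other monitored set: H = 0 so lam_prior = 1/3
  expect_equal(buffer_lam(b)[2], 1 / 3)
  expect_equal(buffer_lam(b)[1], 0.4 * (2 / 3))
})

test_that("eviction removes the least recently used set and keeps its strategy", {
  sets <- list(make_ts(1, flat(), lam = 0.25, mu = 0.25, last = 5L),
               make_ts(2, flat(), lam = 0.25, mu = 0.25, last = 40L),
               make_ts(3, flat(), lam = 0.25, mu = 0.25, last = 90L),
               make_ts(4, flat(), lam = 0.20, mu = 0.20, last = 91L))
  buf <- monitoring_buffer(3, sets)
  ev <- evict_if_full(buf, long_term_memory())
  expect_equal(buffer_ids(ev$buf), c(2L, 3L, 4L))
  expect_equal(ltm_size(ev$ltm), 1L)
  expect_equal(ev$ltm$strategies[[1]]$id, 1L)
  expect_equal(ev$buf$lam0 + sum(buffer_lam(ev$buf)), 1, tolerance = 1e-12)

  # capacity not exceeded: no eviction
  buf2 <- monitoring_buffer(3, sets[1:3])
  ev2 <- evict_if_full(buf2, long_term_memory())
  expect_equal(length(ev2$buf$tasksets), 3L)
  expect_equal(ltm_size(ev2$ltm), 0L)

  # LRU tie broken by smallest id
  sets3 <- list(make_ts(7, flat(), lam = 0.2, mu = 0.2, last = 5L),
                make_ts(2, flat(), lam = 0.2, mu = 0.2, last = 5L),
                make_ts(3, flat(), lam = 0.3, mu = 0.3, last = 9L),
                make_ts(4, flat(), lam = 0.2, mu = 0.2, last = 12L))
  ev3 <- evict_if_full(monitoring_buffer(3, sets3), long_term_memory())
  expect_equal(ev3$ltm$strategies[[1]]$id, 2L)
})

test_that("an evicted strategy is recollectable through probe creation", {
  q <- matrix(runif(12), 3, 4)
  victim <- make_ts(1, matrix(0.9, 3, 4), lam = 0.2, mu = 0.2,
                    n_cues = 2L, contextual = c(1, 0), last = 1L)
  victim$selective <- q
  others <- list(make_ts(2, flat(), lam = 0.3, mu = 0.3, n_cues = 2L,
                         contextual = c(0, 1), last = 10L),
                 make_ts(3, flat(), lam = 0.3, mu = 0.3, n_cues = 2L,
                         contextual = c(0, 1), last = 20L))
  buf <- monitoring_buffer(2, c(list(victim), others))
  ev <- evict_if_full(buf, long_term_memory())
  expect_false(1L %in% buffer_ids(ev$buf))
  probe <- create_probe(ev$ltm, 9, eta = 0, cue = 1L, n_cues = 2L)
  expect_equal(probe$selective, q)
})

test_that("long-term memory never shrinks", {
  ltm <- long_term_memory()
  sizes <- integer(0)
  for (i in 1:5) {
    ltm <- ltm_store(ltm, make_ts(i, flat()))
    sizes <- c(sizes, ltm_size(ltm))
  }
  ltm <- ltm_store(ltm, make_ts(3, flat()))  # refresh, not append
  sizes <- c(sizes, ltm_size(ltm))
  expect_equal(sizes, c(1L, 2L, 3L, 4L, 5L, 5L))
})
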