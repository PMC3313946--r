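test_that("null predictive likelihood is uniform over observed outcomes", {
  expect_equal(null_predictive_likelihood(2), 0.5)
  expect_equal(null_predictive_likelihood(1), 1)
  expect_equal(null_predictive_likelihood(4), 0.25)
  expect_error(null_predictive_likelihood(0), "undefined")
})

test_that("context-sensitivity bias inflates volatility only on cue changes", {
  expect_equal(effective_volatility(0.03, 0.55, cue_changed = FALSE), 0.03)
  expect_equal(effective_volatility(0.03, 0, cue_changed = TRUE), 0.03)
  expect_equal(effective_volatility(0.03, 0.55, cue_changed = TRUE), 0.5635)
  # stays below 1 for any bias
  expect_lt(effective_volatility(0.9, 1, cue_changed = TRUE), 1 + 1e-12)
})

test_that("transition matrix is stochastic with uniform off-diagonal mass", {
  expect_equal(transition_matrix(3, 0), diag(4))
  expect_equal(transition_matrix(1, 0.03),
               matrix(c(0.97, 0.03, 0.03, 0.97), 2))
  for (n in 1:5) {
    for (tau in c(0.01, 0.5)) {
      tm <- transition_matrix(n, tau)
      expect_equal(colSums(tm), rep(1, n + 1))
      expect_equal(rowSums(tm), rep(1, n + 1))
    }
  }
})

test_that("ex-ante update propagates ex-post reliabilities", {
  p_pos <- matrix(0.9, 1, 4)
  buf <- monitoring_buffer(2, list(make_ts(1, p_pos, lam = 0.8, mu = 0.8)))
  expect_equal(buf$mu0, 0.2)
  # zero volatility: identity propagation
  b0 <- update_ex_ante(buf, 0)
  expect_equal(c(b0$lam0, buffer_lam(b0)), c(0.2, 0.8))
  # two-state Markov propagation
  b1 <- update_ex_ante(buf, 0.03)
  expect_equal(buffer_lam(b1), 0.8 * 0.97 + 0.2 * 0.03)
})

test_that("ex-post update is a Bayes step against the null predictor", {
  p_pos <- matrix(0.9, 1, 4)
  buf <- monitoring_buffer(2, list(make_ts(1, p_pos, lam = 0.5, mu = 0.5)))
  b <- update_ex_post(buf, 1, 1, 2, gamma0 = 0.5)
  expect_equal(buffer_mu(b), 0.45 / 0.70, tolerance = 1e-12)
  # uninformative likelihood leaves reliabilities unchanged
  p_flat <- matrix(0.5, 1, 4)
  buf2 <- monitoring_buffer(2, list(make_ts(1, p_flat, lam = 0.3, mu = 0.3),
                                    make_ts(2, p_flat, lam = 0.4, mu = 0.4)))
  b2 <- update_ex_post(buf2, 1, 2, 2, gamma0 = 0.5)
  expect_equal(buffer_mu(b2), c(0.3, 0.4), tolerance = 1e-12)
  expect_equal(b2$mu0, 0.3, tolerance = 1e-12)
})

test_that("reliability recursion equals the exact forward algorithm", {
  set.seed(42)
  for (n_sets in 2:4) {
    p_pos <- lapply(seq_len(n_sets), function(i) {
      matrix(runif(12, 0.1, 0.9), 3, 4)
    })
    mu_init <- runif(n_sets + 1, 0.2, 1)
    mu_init <- mu_init / sum(mu_init)
    sets <- lapply(seq_len(n_sets), function(i) {
      make_ts(i, p_pos[[i]], lam = 0, mu = mu_init[i + 1])
    })
    buf <- monitoring_buffer(n_sets, sets, mu0 = mu_init[1])
    n_trials <- 50L
    s_seq <- sample(3, n_trials, TRUE)
    a_seq <- sample(4, n_trials, TRUE)
    o_seq <- sample(2, n_trials, TRUE)
    tau_seq <- runif(n_trials, 0.01, 0.2)
    lik <- t(vapply(seq_len(n_trials), function(t) {
      c(0.5, vapply(p_pos, function(pp) {
        if (o_seq[t] == 2) pp[s_seq[t], a_seq[t]] else 1 - pp[s_seq[t], a_seq[t]]
      }, 0))
    }, numeric(n_sets + 1)))
    oracle <- oracle_forward(mu_init, tau_seq, lik)
    for (t in seq_len(n_trials)) {
      buf <- update_ex_ante(buf, tau_seq[t])
      expect_lt(max(abs(c(buf$lam0, buffer_lam(buf)) - oracle$lam[t, ])),
                1e-12)
      buf <- update_ex_post(buf, s_seq[t], a_seq[t], o_seq[t], gamma0 = 0.5)
      expect_lt(max(abs(c(buf$mu0, buffer_mu(buf)) - oracle$mu[t, ])), 1e-12)
    }
  }
})

test_that("reliabilities stay normalized after arbitrary update sequences", {
  set.seed(7)
  p_pos <- matrix(runif(12, 0.05, 0.95), 3, 4)
  buf <- monitoring_buffer(3, list(make_ts(1, p_pos, mu = 0.3),
                                   make_ts(2, 1 - p_pos, mu = 0.3)))
  for (t in 1:100) {
    buf <- update_ex_ante(buf, runif(1, 0.01, 0.5))
    expect_equal(buf$lam0 + sum(buffer_lam(buf)), 1, tolerance = 1e-10)
    buf <- update_ex_post(buf, sample(3, 1), sample(4, 1), sample(2, 1), 0.5)
    expect_equal(buf$mu0 + sum(buffer_mu(buf)), 1, tolerance = 1e-10)
    expect_lte(sum(buffer_lam(buf) > 0.5), 1L)
  }
})

test_that("consistent evidence makes reliability non-decreasing at zero volatility", {
  p_pos <- matrix(0.9, 1, 4)
  buf <- monitoring_buffer(1, list(make_ts(1, p_pos, mu = 0.2)))
  mu_prev <- 0.2
  for (t in 1:30) {
    buf <- update_ex_ante(buf, 0)
    buf <- update_ex_post(buf, 1, 1, 2, gamma0 = 0.5)  # positive outcome
    expect_gte(buffer_mu(buf), mu_prev)
    mu_prev <- buffer_mu(buf)
  }
  expect_gt(mu_prev, 0.99)
})

test_that("chance-level predictions are a fixed point of the filter", {
  p_flat <- matrix(0.5, 3, 4)
  buf <- monitoring_buffer(2, list(make_ts(1, p_flat, mu = 0.25),
                                   make_ts(2, p_flat, mu = 0.35)))
  for (t in 1:20) {
    buf <- update_ex_ante(buf, 0)
    buf <- update_ex_post(buf, sample(3, 1), sample(4, 1), sample(2, 1), 0.5)
  }
  expect_equal(buffer_mu(buf), c(0.25, 0.35), tolerance = 1e-10)
  expect_equal(buf$mu0, 0.4, tolerance = 1e-10)
})
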