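test_that("one-step-ahead likelihood has the closed-form bounds", {
  proto <- generate_recurrent_session(53)
  log <- simulate_agent(probe_params(), proto, seed = 2)
  # uniform-random model: LLH = -T log 4
  expect_equal(one_step_likelihood(rl_params(epsilon = 1), log),
               -nrow(log) * log(4), tolerance = 1e-10)
  # any model: LLH <= 0
  for (p in list(probe_params(), max_params(), forget_params(n = 2),
                 rl_params())) {
    expect_lte(one_step_likelihood(p, log), 0)
  }
})

test_that("BIC penalizes free parameters", {
  expect_equal(bic(0, 0, 10), 0)
  expect_equal(bic(-100, 6, 1000), 241.4465, tolerance = 1e-4)
  expect_lt(bic(-50, 3, 500), bic(-50, 4, 500))
  expect_error(bic(-1, 2, 0))
})

test_that("responses are classified against current and preceding mappings", {
  log <- data.frame(
    session_id = "s", seed = 1L,
    condition = "recurrent",
    episode_index = c(1L, 1L, 1L, 2L, 2L, 2L, 2L),
    trial_in_episode = c(0:2, 0:3),
    stimulus = c(1L, 2L, 3L, 1L, 1L, 2L, 3L),
    cue = NA_integer_,
    # episode 1 mapping: 1->2, 2->3, 3->4 ; episode 2 mapping: 1->1, 2->2, 3->3
    correct_response = c(2L, 3L, 4L, 1L, 1L, 2L, 3L),
    response = c(2L, 1L, 4L, 2L, 1L, 4L, 3L),
    outcome = 1L)
  lab <- classify_responses(log)
  expect_equal(lab, c("correct", NA, "correct",
                      "perseverative", "correct", "exploratory", "correct"))
})

test_that("aligned rates partition into correct, perseverative, exploratory", {
  proto <- generate_recurrent_session(61)
  log <- simulate_agent(probe_params(), proto, seed = 9)
  rates <- aligned_rates(log, max_trial = 20)
  expect_true(all(rates$rate_correct >= 0 & rates$rate_correct <= 1))
  sums <- rates$rate_correct + rates$rate_perseverative +
    rates$rate_exploratory
  # partition holds where labels are defined; first-episode NAs shift the
  # perseverative/exploratory denominators only slightly
  expect_true(all(abs(sums - 1) < 0.15))
  # an all-correct log has rate 1 everywhere
  log2 <- log
  log2$response <- log2$correct_response
  r2 <- aligned_rates(log2, max_trial = 15)
  expect_true(all(r2$rate_correct == 1))
})

test_that("pair mutual information matches the plug-in formula", {
  expect_equal(pair_mutual_information(c(40, 10, 10, 40)), 0.278,
               tolerance = 1e-3)
  expect_equal(pair_mutual_information(c(40, 10, 10, 40)),
               pair_mutual_information(c(40, 10, 10, 40)[c(4, 3, 2, 1)]))
  expect_equal(pair_mutual_information(c(50, 0, 0, 50)), 1)
  expect_equal(pair_mutual_information(c(25, 25, 25, 25)), 0)
  set.seed(4)
  big <- table(factor(rbinom(2e4, 1, 0.5), 0:1),
               factor(rbinom(2e4, 1, 0.5), 0:1))
  expect_lt(pair_mutual_information(as.vector(t(big))), 5e-4)
})

test_that("mutual dependence pools within-episode pairs only", {
  log <- data.frame(
    session_id = "s", seed = 1L, condition = "recurrent",
    episode_index = rep(1:10, each = 6),
    trial_in_episode = rep(0:5, 10),
    stimulus = 1L, cue = NA_integer_,
    correct_response = 1L,
    response = rep(c(1L, 1L, 1L, 2L, 2L, 2L), 10),
    outcome = 1L)
  md <- mutual_dependence(log, bin_width = 5, max_trial = 2)
  # 5 within-episode pairs per episode in the first window
  expect_equal(md$n_pairs[md$trial == 1], 50L)
  # pooled pair counts per episode: (1,1)x2, (1,0)x1, (0,0)x2
  expect_equal(md$mi_bits[md$trial == 1],
               pair_mutual_information(c(20, 0, 10, 20)), tolerance = 1e-12)
})

test_that("simulated data are more likely under generating than perturbed parameters", {
  set.seed(3)
  gen <- rl_params(beta = 10, epsilon = 0.05, alpha_s = 0.4)
  alt <- rl_params(beta = 10, epsilon = 0.05, alpha_s = 0.05)
  wins <- 0
  for (i in 1:10) {
    log <- simulate_exp1(gen, i)
    if (one_step_likelihood(gen, log) > one_step_likelihood(alt, log)) {
      wins <- wins + 1
    }
  }
  expect_gte(wins, 9)
})

test_that("RL fitting recovers the generating learning rate", {
  log <- simulate_exp1(rl_params(beta = 30, epsilon = 0.02, alpha_s = 0.4), 7)
  fit <- fit_participant(log, model = "rl", n_starts = 5, seed = 1,
                         maxit = 200)
  expect_lt(abs(fit$estimates[["alpha_s"]] - 0.4), 0.1)
  expect_equal(fit$bic, bic(fit$llh, fit$n_params, fit$n_trials))
})

test_that("fitting is deterministic given data, seed and starts", {
  log <- simulate_exp1(rl_params(alpha_s = 0.3, epsilon = 0.05), 19)
  f1 <- fit_participant(log, model = "rl", n_starts = 2, seed = 5, maxit = 80)
  f2 <- fit_participant(log, model = "rl", n_starts = 2, seed = 5, maxit = 80)
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$llh, f2$llh)
})

test_that("run-level entry points compose simulation, fitting and recovery", {
  out_dir <- tempfile("run")
  cfg <- list(model = "rl", params = list(alpha_s = 0.3, epsilon = 0.05),
              experiment = "exp1_recurrent", n_agents = 2, seed = 42)
  sim <- run_simulate(cfg, out_dir = out_dir)
  expect_true(file.exists(file.path(out_dir, "log.csv")))
  expect_true(file.exists(file.path(out_dir, "summary.json")))
  expect_true(file.exists(file.path(out_dir, "aligned_rates.csv")))
  expect_equal(sort(unique(sim$log$agent)), 1:2)
  smry <- jsonlite::read_json(file.path(out_dir, "summary.json"))
  expect_equal(smry$config$package_version,
               as.character(utils::packageVersion("probetask")))

  log <- read_log(file.path(out_dir, "log.csv"))
  fit <- run_fit(log[log$agent == 1, ], models = "rl", out_dir = out_dir,
                 n_starts = 2, maxit = 60)
  expect_true(file.exists(file.path(out_dir, "model_comparison.csv")))
  expect_equal(fit$comparison$model, "rl")

  # same config twice gives byte-identical logs
  sim2 <- run_simulate(cfg)
  expect_identical(sim$log, sim2$log)

  # schema validation names the missing column
  bad <- log; bad$outcome <- NULL
  path <- file.path(out_dir, "bad.csv")
  utils::write.csv(bad, path, row.names = FALSE)
  expect_error(read_log(path), "outcome")
  unlink(out_dir, recursive = TRUE)
})

test_that("recovery reports include seeds for every replicate", {
  rep <- run_recover(rl_params(alpha_s = 0.35), n_replicates = 2,
                     seed = 9, n_starts = 2, maxit = 60)
  expect_equal(nrow(rep), 2L)
  expect_true(all(!is.na(rep$seed)))
  expect_true("fit_alpha_s" %in% names(rep))
})

test_that("performance optimization finds the better grid point", {
  res <- optimize_performance(
    rl_params(), grid = list(epsilon = c(0.9, 0.001)), n_reps = 3, seed = 2,
    simulate_fn = function(p, s) {
      simulate_agent(p, stationary_protocol(120), seed = s)
    })
  expect_equal(res$best$epsilon, 0.001)
  expect_equal(nrow(res$surface), 2L)
  expect_true(all(res$surface$mean_correct >= 0 &
                    res$surface$mean_correct <= 1))
})

test_that("unknown models and parameters are rejected with clear messages", {
  expect_error(make_agent_params("nonsense"), "unknown model")
  expect_error(make_agent_params("probe", list(gamma = 1)),
               "unknown parameter")
  expect_silent(make_agent_params("forget", list(phi = 0.2)))
})
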