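#' Build an `agent_params` object from a model name and a plain list
#'
#' Convenience dispatcher used by the run-level entry points and the
#' command-line script.
#'
#' @param model One of `"probe"`, `"max"`, `"forget"`, `"rl"`.
#' @param params Named list of parameter overrides (see [probe_params()]).
#' @return An `agent_params` object.
#' @export
make_agent_params <- function(model, params = list()) {
  ctor <- switch(model, probe = probe_params, max = max_params,
                 forget = forget_params, rl = rl_params,
                 stop("unknown model: ", model, call. = FALSE))
  known <- names(formals(ctor))
  bad <- setdiff(names(params), known)
  if (length(bad)) {
    stop("unknown parameter(s) for model '", model, "': ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  do.call(ctor, params)
}

#' Generate the protocols of one experiment
#'
#' @param experiment `"exp1"` (open + recurrent), `"exp1_open"`,
#'   `"exp1_recurrent"`, `"recurrent4"` (four reoccurring mappings) or
#'   `"exp2"` (the two color-cued sessions).
#' @param seed Integer seed.
#' @return A list of `session_protocol` objects.
#' @export
generate_experiment <- function(experiment, seed) {
  s <- split_seed(seed, 2L)
  switch(experiment,
    exp1 = list(open = generate_open_session(s[1L]),
                recurrent = generate_recurrent_session(s[2L])),
    exp1_open = list(open = generate_open_session(s[1L])),
    exp1_recurrent = list(recurrent = generate_recurrent_session(s[1L])),
    recurrent4 = list(recurrent4 = generate_recurrent_session(s[1L], 4L)),
    exp2 = generate_cued_sessions(s[1L]),
    stop("unknown experiment: ", experiment, call. = FALSE))
}

#' Read a run configuration from YAML or JSON
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file with
#'   fields `model`, `params` (named list), `experiment`, `n_agents`,
#'   `seed`.
#' @return The configuration as a named list.
#' @export
read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is required to read YAML configurations",
           call. = FALSE)
    }
    yaml::yaml.load_file(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

resolved_config <- function(config, params) {
  config$params <- unclass(params)
  config$package_version <- as.character(utils::packageVersion("probetask"))
  config
}

#' Simulate agents and write behavioral logs
#'
#' Simulates `n_agents` independent agents (fresh protocols and fresh
#' internal state per agent) on the configured experiment and writes the
#' pooled trial-level log as CSV plus a JSON summary (overall and
#' per-condition correct rates, resolved configuration, package version).
#'
#' @param config Named list (or path read by [read_config()]) with fields
#'   `model`, `params`, `experiment`, `n_agents`, `seed`.
#' @param out_dir Output directory (created if missing); `NULL` to skip
#'   writing.
#' @return Invisibly, a list with `log` (the pooled `data.frame`) and
#'   `summary`.
#' @export
run_simulate <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_config(config)
  params <- make_agent_params(config$model, as.list(config$params))
  n_agents <- if (is.null(config$n_agents)) 1L else as.integer(config$n_agents)
  agent_seeds <- split_seed(config$seed, n_agents)
  logs <- lapply(seq_len(n_agents), function(i) {
    protos <- generate_experiment(config$experiment, agent_seeds[i])
    sim_seeds <- split_seed(agent_seeds[i] + 1L, length(protos))
    pooled <- do.call(rbind, lapply(seq_along(protos), function(j) {
      simulate_agent(params, protos[[j]], seed = sim_seeds[j])
    }))
    pooled$agent <- i
    pooled
  })
  log <- do.call(rbind, logs)
  by_cond <- tapply(log$is_correct, log$condition, mean)
  summary <- list(
    config = resolved_config(config, params),
    n_trials = nrow(log),
    correct_rate = mean(log$is_correct),
    correct_rate_by_condition = as.list(by_cond))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(log, file.path(out_dir, "log.csv"), row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    rates <- aligned_rates(log)
    utils::write.csv(rates, file.path(out_dir, "aligned_rates.csv"),
                     row.names = FALSE)
  }
  invisible(list(log = log, summary = summary))
}

#' Read a behavioral log CSV, validating the schema
#'
#' @param path CSV path.
#' @return The log `data.frame`.
#' @export
read_log <- function(path) {
  log <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("session_id", "condition", "episode_index",
                "trial_in_episode", "stimulus", "cue", "response", "outcome",
                "correct_response")
  missing <- setdiff(required, names(log))
  if (length(missing)) {
    stop("behavioral log is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  log
}

#' Fit one or several models to a behavioral log and compare them
#'
#' Runs [fit_participant()] per model (and per agent if the log contains an
#' `agent` column) and assembles a comparison table with LLH, LS and BIC.
#'
#' @param log A behavioral log `data.frame` or a CSV path.
#' @param models Character vector of model names.
#' @param method `"llh"` or `"ls"`.
#' @param out_dir Optional output directory for JSON/CSV reports.
#' @param ... Passed to [fit_participant()].
#' @return Invisibly, a list with `fits` (nested list) and `comparison`
#'   (`data.frame`).
#' @export
run_fit <- function(log, models = "probe", method = "llh", out_dir = NULL,
                    ...) {
  if (is.character(log)) log <- read_log(log)
  agents <- if ("agent" %in% names(log)) unique(log$agent) else NA
  rows <- list(); fits <- list()
  for (ag in agents) {
    sub <- if (is.na(ag)) log else log[log$agent == ag, ]
    for (m in models) {
      fit <- fit_participant(sub, model = m, method = method, ...)
      fits[[paste0(m, "_", ag)]] <- fit
      rows[[length(rows) + 1L]] <- data.frame(
        agent = ag, model = m, llh = fit$llh, ls = fit$ls, bic = fit$bic,
        n_params = fit$n_params, n_trials = fit$n_trials,
        stringsAsFactors = FALSE)
    }
  }
  comparison <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(comparison, file.path(out_dir, "model_comparison.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      lapply(fits, function(f) {
        list(model = f$model, method = f$method,
             estimates = as.list(f$estimates), llh = f$llh, ls = f$ls,
             bic = f$bic)
      }),
      file.path(out_dir, "fits.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  invisible(list(fits = fits, comparison = comparison))
}

#' Simulate-then-fit parameter and model recovery
#'
#' Simulates replicates from a generating model, refits, and reports
#' per-replicate generating versus recovered parameters (and, when several
#' candidate models are given, the BIC-winning model per replicate).
#'
#' @param gen_params Generating `agent_params`.
#' @param n_replicates Number of simulated participants.
#' @param fit_models Models to fit to each replicate.
#' @param seed Master seed; each replicate's seeds are derived from it and
#'   recorded in the report.
#' @param out_dir Optional output directory.
#' @param ... Passed to [fit_participant()].
#' @return Invisibly, a `data.frame` with one row per replicate x model.
#' @export
run_recover <- function(gen_params, n_replicates = 5L,
                        fit_models = gen_params$model, seed = 1L,
                        out_dir = NULL, ...) {
  rep_seeds <- split_seed(seed, n_replicates)
  rows <- list()
  for (i in seq_len(n_replicates)) {
    log <- simulate_exp1(gen_params, rep_seeds[i])
    for (m in fit_models) {
      fit <- fit_participant(log, model = m, seed = rep_seeds[i], ...)
      row <- data.frame(replicate = i, seed = rep_seeds[i], model = m,
                        llh = fit$llh, bic = fit$bic,
                        stringsAsFactors = FALSE)
      for (nm in names(fit$estimates)) {
        row[[paste0("fit_", nm)]] <- unname(fit$estimates[nm])
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  report <- do.call(rbind, lapply(rows, function(r) {
    r[setdiff(unique(unlist(lapply(rows, names))), names(r))] <- NA
    r
  }))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(report, file.path(out_dir, "recovery.csv"),
                     row.names = FALSE)
  }
  invisible(report)
}
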