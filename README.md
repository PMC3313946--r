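# probetask

Simulation and fitting toolkit for models of human executive control over
behavioral strategies ("task sets"), built around the PROBE model: a
bounded monitoring buffer tracks the Bayesian reliability of a few
candidate task sets against an explicit null hypothesis, creates *probe*
task sets by recombining strategies stored in long-term memory whenever no
monitored set appears reliable, and confirms or discards those probes by
hypothesis testing. The rival MAX, FORGET and flat reinforcement-learning
models run behind the same agent interface, together with generators for
the stochastic episode protocols used to study task-set switching and the
fitting/comparison machinery (one-step-ahead likelihood, least squares,
BIC).

## The model in brief

A task set `i` holds a selective mapping `Q_i(s, a)` (expected reward,
delta-rule learning at rate `alpha_s`), a predictive mapping
`P_i(o | s, a)` (regularized outcome frequency), and a contextual mapping
`F_i(cue)`. Its *ex-ante* reliability `lambda_i(t)` — the probability that
it matches the current hidden state of the environment — is propagated
each trial through a volatility transition model (per-trial change
probability `tau`) and reweighted by contextual cues; after feedback the
*ex-post* reliability is the Bayes update

    mu_i  ∝  lambda_i · P_i(o | s, a),      mu_0  ∝  lambda_0 · gamma_0,

where `lambda_0` is the null mass ("no monitored set matches") and
`gamma_0` the uniform outcome predictor. Actor selection is satisficing:
the unique set with `lambda > 0.5` acts; if none qualifies a probe is
created from the long-term-memory mixture
`(1 - eta) * sum_k w_k M_k + eta * U` with maximum-entropy prior
reliability `1/(2 + exp(H))`, optionally biased toward the threshold by
the confirmation bias `theta`. Actions come from an epsilon-softmax with
inverse temperature `beta` and lapse `epsilon`.

## Worked example

```r
library(probetask)

protocol <- generate_recurrent_session(seed = 1)   # 25 episodes, 3 mappings
log <- simulate_agent(probe_params(), protocol, seed = 2)

mean(log$is_correct)
#> [1] 0.8351254

head(aligned_rates(log, max_trial = 5)[, c("condition", "trial",
                                           "rate_correct")])
#>   condition trial rate_correct
#> 1 recurrent     1         0.04
#> 2 recurrent     2         0.04
#> 3 recurrent     3         0.24
#> 4 recurrent     4         0.32
#> 5 recurrent     5         0.32
```

The agent scores 84% correct across the session: near-chance in the first
trials of each episode (the mapping just changed covertly), then rising
within a few trials as the matching task set is retrieved through its
outcome predictions. `mutual_dependence()` computes the companion
statistic — the mutual information between successive correct decisions in
five-trial sliding windows — whose early-episode peak in recurrent
sessions is the signature of retrieving a whole mapping from a single
feedback.

Fitting and model comparison:

```r
fit <- fit_participant(log, model = "probe")   # LLH, multi-start, N enumerated
run_fit(log, models = c("probe", "max", "forget", "rl"))  # BIC table
```

A thin command-line front end is available at `exec/probetask`
(`simulate`, `fit`, `recover`, `optimize` subcommands; configuration via
YAML/JSON).

## Behavioral log format

CSV, UTF-8, comma-separated, one row per trial: `session_id`, `condition`
(`open`/`recurrent`/`rehearsal`/`control`/`transfer`), `episode_index`
(1-based), `trial_in_episode` (0-based), `stimulus` (1..3), `cue`
(1-based color cue or empty), `response` (1..4), `outcome` (1 = positive
feedback), `correct_response`, `is_correct`, `is_perseverative` (empty in
a session's first episode, where "perseverative" is undefined), `seed`.

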