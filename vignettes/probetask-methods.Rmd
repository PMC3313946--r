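---
title: "Task-set monitoring, creation and selection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Task-set monitoring, creation and selection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(probetask)
```

## The problem

In changing, open-ended environments a decision-maker must continuously
arbitrate between three options: keep adjusting the strategy currently
driving behavior, switch to another strategy learned earlier, or build a
new strategy from scratch. `probetask` implements a family of computational
models of this executive arbitration for a standard laboratory protocol:
on each trial a stimulus (one of three) is shown, the agent presses one of
four keys, and feedback is positive with probability 0.9 if the key is the
correct one for the current hidden stimulus–response mapping and with
probability 0.1 otherwise. The mapping changes covertly every 36–54 trials
(an *episode*). Across episodes mappings may be all new (*open* session) or
may reoccur (*recurrent* sessions), and stimulus color may cue the mapping
(*cued* sessions with control/transfer/open test episodes).

## Task sets and reliability monitoring

A *task set* bundles three internal mappings: a **selective** mapping
`Q(s, a)` of expected reward values learned by the delta rule, a
**predictive** mapping `P(o | s, a)` of outcome likelihoods, and a
**contextual** mapping `F(cue)` giving the likelihood that the set is
reliable when a cue is observed.

The monitoring buffer tracks at most `N` task sets plus an explicit null
hypothesis ("no monitored set matches the current hidden state") whose
outcome predictor is uniform over the observed outcome kinds
(`gamma0 = 1/2` here). Reliability is updated by standard Bayesian
filtering at two points per trial:

* **ex-ante** (before acting): the previous ex-post reliabilities are
  propagated through a transition model in which each hypothesis keeps its
  identity with probability `1 - tau` and the escaping volatility mass is
  spread uniformly over the other hypotheses; with a cue, each set is then
  reweighted by `F_i(cue)` (the null by the neutral baseline `1/n_cues`);
* **ex-post** (after feedback): each hypothesis is reweighted by its
  likelihood of the observed outcome, `P_i(o | s, a)` for sets and
  `gamma0` for the null.

Both updates renormalize, so `lambda0 + sum(lambda_i) = 1` holds at all
times, which guarantees that at most one set can exceed the selection
criterion. The test suite checks the recursion against an independently
written exact forward algorithm to `1e-12`.

Actor selection is *satisficing*: a set with `lambda > 0.5` (more likely
reliable than not) is the actor. If none qualifies, a **probe** task set is
created: its mappings are a convex mixture of all strategies stored in
long-term memory (weighted by contextual likelihood of the current cue)
and the random strategy, with mixture weight `eta` (the *recollection
entropy*). The probe receives the maximum-entropy prior reliability
`1/(2 + exp(H))` — where `H` is the entropy of the other monitored sets'
normalized reliabilities — optionally biased toward the 0.5 threshold by
the *confirmation bias* `theta`. The probe acts until the hypothesis test
resolves: it is **confirmed** (stored in long-term memory; the least
recently used set is evicted if the buffer exceeds `N`) when it becomes
reliable first, or **discarded without trace** when another set becomes
reliable first — that is how previously learned sets are retrieved.

## Rival models

* **MAX** removes the hypothesis test: the most reliable set is the actor
  as long as it beats the null mass; otherwise a new set is created with
  prior reliability equal to the null level, which makes it immediately
  the most reliable hypothesis, so creation is auto-confirmed.
* **FORGET** removes creation: a fixed collection of `N` sets, a softmax
  actor choice over reliabilities (inverse temperature `beta_actor`), and
  decay of unused strategies toward the random strategy at rate `phi`.
  Learning is reliability-weighted in every set (actor-only learning is
  available as a configuration and gives virtually identical behavior).
  With `N = 1` and actor-only learning FORGET reduces exactly to the flat
  RL baseline (verified by trajectory identity); `phi = 0` gives the
  multiple-actor case, and `N = 2` with large `phi` an
  uncertainty-monitoring scheme tracking only the actor against chance.
* **Flat RL** holds a single actor learning stimulus–response values (and,
  with cues, a mixture `(1-omega) Q_SR + omega Q_SCR` mixed at the value
  level).

Action selection everywhere is an epsilon-softmax with inverse temperature
`beta` and lapse rate `epsilon`; rewards are coded 1 (positive) / 0
(negative) and `Q` tables start at the uninformative `1/n_a`.

## The predictive mapping: design rationale

The sources for this model family describe the predictive mapping only as
a "regularized" outcome likelihood, so its concrete form is a design
choice of this package, and it turned out to be the single most
consequential one. Three properties are needed at once:

1. **Converged predictions must sit near the true 90/10 rates.** A plain
   exponential moving average at the selective learning rate tracks recent
   streaks — after a run of positives `P(neg)` collapses toward zero, so a
   single noisy feedback destroys the actor's reliability and the agent
   churns through probes.
2. **Early observations must move a fresh cell quickly**, or probes can
   never become reliable within an episode.
3. **Task sets must predict failure for actions they have not learned.**
   Under an injective mapping exactly one of `n_a` actions is correct, so
   the random-strategy baseline assigns an untried action success
   probability `pred_prior = 1/n_a`. Without this structure, outcomes of
   most probe-phase actions carry no information about *which* stored set
   matches the environment, and retrieval of a reoccurring mapping takes
   tens of trials instead of a few.

The implementation therefore keeps, per `(s, a)` cell, a probability row
and an effective observation weight `w` (initialized at `pred_weight0`,
default 2, counting the baseline as weak pseudo-observations):
`w' = (1 - alpha_p) w + 1` and `P <- P + (1[o] - P)/w'`. Early steps are
large (Laplace-like), late steps approach the leak rate `alpha_p`
(default 0.02, stationary weight 50), and the row converges to the
long-run outcome frequency with small variance. Probe creation mixes
stored probability tables but resets the weights: recollection restores
content, not confidence.

## Numerical choices and degenerate inputs

* All probabilities are floored at `1e-12` before renormalization, so no
  hypothesis becomes an absorbing zero.
* Removing a set (probe discard, LRU eviction) renormalizes the remaining
  reliability mass proportionally; LRU ties break toward the smallest id.
* With an empty history all hypotheses are presumed equally reliable; an
  empty buffer puts all mass on the null, which triggers creation on the
  first trial.
* The number of observed outcome kinds (for `gamma0`) is the hard count
  of distinct outcomes seen so far in the session.
* Perceived volatility is a fixed configurable `tau` (default 0.03,
  matching the protocols' average episode change rate); the
  context-sensitivity bias inflates it to `tau + delta (1 - tau)` on
  cue-change trials, which stays below 1 for any `delta in [0, 1]`.

## Synthetic protocols

`generate_open_session()` orders all 24 injective mappings so that two
successive mappings share no association (a randomized greedy walk on the
non-overlap graph, which is dense enough that restarts always succeed) and
reuses the first mapping in episode 25. `generate_recurrent_session()`
draws the episode sequence as a random Eulerian circuit on the
mapping-transition multigraph, which yields exactly the 8/8/9 repetition
counts, exactly equalized transition frequencies, and no immediate
repeats. `generate_cued_sessions()` adds the color-cue layer (two mappings
with one cue each, one with two cues and at most one within-episode cue
switch) and the 13-rehearsal + 4-control/6-transfer/2-open test session,
with all mappings drawn as rows of a randomized Latin square (hence fully
incongruent). Episode lengths are drawn uniformly from 36..54 (the sources
state only the range); stimulus sequences are shuffled balanced blocks, so
every stimulus appears in every episode. Trial timing (stimulus asynchrony,
response deadline) is not simulated.

What the generator does *not* emulate about real data: response omissions
and reaction times, motivational drift across a session, and any
participant-specific counterbalancing. Passing tests on synthetic logs
therefore validate the algorithmic claims, not parameter values for any
particular human dataset.

## Fitting

`fit_participant()` maximizes the one-step-ahead log-likelihood of the
observed responses (the model is conditioned on the actual response and
outcome of every trial) or minimizes per-position least squares between
observed correct frequencies and predicted correct probabilities.
Continuous parameters are optimized by multi-start Nelder–Mead on log- or
logit-transformed coordinates; the integer capacity `N` is enumerated.
FORGET's stochastic actor choice is marginalized for prediction and its
decay applied in expectation, so all objectives are deterministic given
the data and the seed. `BIC = -2 LLH + k log(n_trials)` counts `N` as a
free parameter for the task-set models.

In recovery simulations on two-session synthetic experiments the capacity
`N` and the learning rate `alpha_s` are recovered reliably; the inverse
temperature `beta` is weakly identified whenever behavior is near-greedy
(any sufficiently large `beta` predicts almost the same choices), which is
a property of the protocol rather than of the optimizer.

## Simulation scale and reproducibility

A single simulated experiment (one open plus one recurrent session, about
2,250 trials) takes a few milliseconds in the compiled engine, so the
package-level studies use hundreds of replicates per condition: the
acceptance script uses 200 replicates per capacity value, 800 per
recollection-entropy value and 400 per learning-rate value, with
replicate seeds shared across grid points so comparisons are paired. A
pure-R reference engine composed from the exported per-operation functions
produces bit-identical trajectories for any seed (both engines draw from
R's RNG in the same order), which the test suite exploits for
cross-validation.

## Known limitations

* With the published optimal parameters (`N = 3`, `eta = 1`, `theta = 0`,
  `beta = 30`, `epsilon = 0`, `alpha_s = 0.4`) this implementation attains
  a mean correct-response proportion of about 75% on the uncued
  two-session protocol, a few points below the 80% reported for the
  original implementation. Sweeps over every internal constant of the
  predictive model, the volatility, and alternatives for the transition
  and value-normalization structure plateau at this level. The residual
  cost is churn intrinsic to the satisficing criterion under 90/10
  feedback: a just-confirmed actor sits barely above the 0.5 threshold
  with likelihood ratios bounded by 1.8 per trial, so occasional noisy
  feedback triggers probe creations and restarts about once per episode.
  The qualitative structure of the optimum (capacity 3, maximal
  recollection entropy, learning rate 0.4) is reproduced exactly, and the
  same implementation run at the published best-fitting human parameters
  lands a similar distance below the published human performance,
  suggesting a uniform offset in unreported implementation details of the
  original predictive/volatility machinery rather than a structural
  difference.
* The volatility estimator is a fixed parameter, not a hierarchical
  learner; continuous cue spaces are not supported.
* Outcome-devaluation recalibration of recollected strategies (model-based
  re-planning at creation) is out of scope; no protocol here exercises it.

## A worked example

```{r, eval = FALSE}
protocol <- generate_recurrent_session(seed = 1)
log <- simulate_agent(probe_params(), protocol, seed = 2)
mean(log$is_correct)
aligned_rates(log, max_trial = 10)[, c("condition", "trial", "rate_correct")]
```
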