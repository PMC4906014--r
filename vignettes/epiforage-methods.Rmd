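---
title: "Epistemic foraging by active inference: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Epistemic foraging by active inference: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiforage)
```

## The task

An agent must categorize a 2x2 visual scene it can only sample one
location at a time, through saccadic eye movements. Every scene contains a
bird and one companion cue, and the category is carried purely by their
spatial relation: a seed horizontally adjacent to the bird means *feed*, a
cat adjacent means *flee*, and a seed diagonally opposite the bird means
*wait*. Absolute positions are nuisance: each category's base layout can be
reflected about the vertical axis (`flip_lr`) and/or the horizontal axis
(`flip_ud`), giving 3 x 2 x 2 = 12 distinct scenes. The agent starts at
central fixation, can saccade to the four quadrants, and can report its
decision at one of three choice locations, which return `right` or `wrong`
feedback.

The generative model is a discrete partially observed Markov decision
process with two outcome modalities — *what* is seen (null, seed, bird,
cat, right, wrong) and *where* it is seen (8 locations) — and four
hidden-state factors: context (3), sampled location (8), and the two
reflections (2 x 2), i.e. 96 joint hidden states. All likelihoods are
deterministic one-hot maps; only the location factor is controllable
(saccade `k` moves the eye to location `k` from anywhere), the others are
static. Priors are uniform except the initial location (central fixation).

Base layouts place the bird at the upper right; its companion sits at the
upper left for feed/flee and at the lower left (diagonal) for wait. This
convention is fixed once so that serialized traces are comparable across
runs; only the adjacency/diagonal relations are meaningful.

## Perception: mean-field variational inference

Beliefs about the hidden trajectory factorize over factors and epochs
(a mean-field approximation). For each candidate policy the marginals of
observed epochs are updated by a log-space relaxation,

`s <- softmax(ln s + kappa * (v - ln s))`, `kappa = 0.25`,

where the message `v` collects the forward transition message (`ln D` at
the first epoch, else `ln B s` of the previous epoch), the backward message
from the next *observed* epoch, and the observation message. Updates sweep
all observed epochs — beliefs about the past keep being revised by later
outcomes (postdiction) — for at most 16 iterations, stopping early once the
free-energy decrease falls below 1/128. That scheduling is itself the
model's reaction-time proxy: `score_trial()` reports mean variational
iterations per epoch, a hardware-independent quantity, instead of
wall-clock time.

Two numerical choices deserve emphasis, because both were forced by
failure modes we could reproduce at will:

* **Observation messages contract before the log.** The message to factor
  `n` is `ln E_q(others)[P(o | s)]`, not `E_q(others)[ln P(o | s)]`. With
  one-hot likelihoods and a log floor of `1e-16`, the log-then-contract
  form multiplies the floor (-36.8 nats) by the companion factors' belief
  mass, so any residual uncertainty in one factor injects enormous
  gradients into another. The temporal mean field then locks into
  internally inconsistent basins — e.g. explaining a seed at the lower
  left as "wait, no reflection" at one epoch while explaining a bird at
  the lower right as "wait, reflected" at the next — and roughly half of
  all trials end in a wrong report. Contract-then-log bounds every message
  by the log of an averaged likelihood; a state is pushed to the floor
  only when it is inconsistent with the observation under *every*
  configuration of the other factors.
* **Prediction epochs are propagated, not iterated.** For epochs beyond
  the last observation the policy-conditional predictive has a closed
  form: static factors carry the current marginal forward (identity
  transitions) and the location factor is the policy's one-hot target. At
  that point the exact backward gradient through a prediction epoch is
  constant, so prediction epochs neither receive updates nor send
  backward messages. Iterating them with `ln s` messages instead drags
  the tail of the trajectory toward uniform and leaves spurious
  complexity in `F` (about 0.7 nats on one-factor problems, breaking the
  identity `F = -ln P(o)` at the exact posterior).

The log floor (`ln x` evaluated as `ln max(x, 1e-16)`) is needed because
the deterministic likelihoods contain exact zeros. A side effect is that
`F` can dip a few hundredths of a nat below the ideal evidence bound when
a vanishing amount of belief mass sits on states the exact posterior
excludes; tests account for that slack explicitly.

## Policy evaluation, precision, and action

Policies are built on the fly: the executed saccade history extended by
each of the eight candidate next actions. For each candidate the expected
free energy accumulates over all remaining epochs,

`G = sum over future epochs and modalities of [risk + ambiguity]`,

with risk the KL divergence from predicted outcomes to preferred outcomes
`softmax(C)` and ambiguity the expected conditional outcome entropy (zero
here, by one-hot likelihoods). Equivalently `G` is negative epistemic value
(state-outcome mutual information) minus extrinsic value, up to the
preference normalization; `expected_free_energy()` returns all four
components and `brute_force_G()` re-derives `G` by explicit summation over
all 96 states and outcomes as an oracle. Preferences are
`C1 = (0, 0, 0, 0, c, -2c)` over the *what* modality — correct feedback is
`exp(c)` times more expected than any cue, incorrect feedback is strongly
unexpected — and flat over locations.

Policy beliefs are `pi = softmax(-F - gamma * G)` with precision
`gamma = 1/beta`. When an outcome arrives, the observed location collapses
`pi` onto the executed candidate (exactly, up to the log floor), while
`pi0 = softmax(-gamma * G)` keeps weighing the alternatives by their
planning-time expected free energies; the temperature then relaxes to the
fixed point of `beta = beta_prior + (pi - pi0) . G` (damped half-steps,
`|delta beta| < 1e-4`, at most 8 inner iterations, `beta > 1/64`). The
resulting `gamma` trace behaves like a phasic dopamine signal: confirming
an action that was much better than the prior average over candidates
yields a burst, and `dopamine_signal()` mixes `gamma` with its rate of
change (weight 4) for display. One caveat is documented as a limitation
below.

Action closes the loop: predicted outcome distributions of all candidates
are mixed by `pi` (a Bayesian model average), and the executed saccade
minimizes the KL divergence from that prediction to the outcome implied by
applying each action's transition to the averaged current state. The
deterministic mode (`action_mode = "argmin"`, ties to the lowest index) is
the default for reproducible single trials; the stochastic mode samples
from `softmax(-alpha * KL)` (`action_precision = alpha`, default 1), whose
infinite-`alpha` limit is the argmin. The KL rule has two properties worth
noting: it naturally suppresses choice saccades until the Bayesian model
average actually predicts feedback outcomes (any predicted mass on cues
meets the one-hot implied distribution's floor), and it suppresses
revisits to locations whose content is already certain. Both are central
to the preference-by-precision phenomenology.

## What the simulator reproduces

With defaults (`c = 2`, `beta_prior = 1`, `T = 6`), a flee scene with no
reflections is reported correctly within five saccades; across 32 random
scenes (six saccades allowed) 32 of 32 reports are correct at these
settings, and about 85% of inference epochs converge within the 16
iteration budget. A single null observation at the lower-right quadrant
leaves the exact context posterior uniform (P(wait) = 1/3 by enumeration
of the 12 configurations), while the mean-field marginal suppresses wait
far below 1/3 — the overconfidence signature of factorized inference:
representing "wait with exactly one unknown reflection" needs a
correlation between context and reflection factors the mean field cannot
carry. This is also why wait scenes dominate the residual errors.

`run_sweep()` crosses preference strengths (0 to 4, 8 levels) with prior
temperatures `beta` log-spaced over `2^6 .. 2^-4`. The range is our free
choice, set so the implied precisions span near-uniform to
near-deterministic policy selection at the G spreads this task produces
(about 10-20 nats between exploratory and premature-choice policies at
high preference); the original suggestion of `2^3` at the low end leaves
`gamma * delta G` well above 1 and almost no behavioral effect of
precision. At the highest preference, the lowest precision level yields no
decisions within eight saccades (decision time pinned at 8, accuracy
scored as incorrect), while the highest precision level decides in 3-4
saccades with near-perfect accuracy; accuracy increases along the
precision axis.

Simulated electrophysiology is read directly off the belief updates:
`firing_raster()` arranges per-iteration expectations as units tuned to
(state, represented epoch) over 16 bins per 250 ms epoch (diagonal blocks
are current beliefs, off-diagonal postdiction and prediction);
`simulated_lfp()` takes first temporal differences and band-limits the
unit average with a zero-phase second-order Butterworth band-pass with
half-power points at 2 and 8 Hz (the "4 Hz" band; applied forward and
backward via `filtfilt`, so the effective magnitude response is squared).

## Study conditions and problem sizes

The synthetic scenes are the study conditions themselves: contexts and
reflections drawn uniformly and independently, as in the simulated
experiments being reproduced. Single-trial demonstrations use `T = 6`
(five saccades); the 32-trial battery uses `T = 7` (six saccades after
fixation); sweeps use `T = 9` (up to eight saccades) with non-choosing
trials scored incorrect at decision time 8. The test suite exercises the
sweep corners at 128 trials per cell and a reduced four-level precision
column at 32 trials per cell; `scripts/acceptance.R` recomputes the
convergence percentage from 32 fresh trials. These sizes keep the full
suite within a few minutes on a single core while leaving the acceptance
quantities' sampling error well inside their tolerances; nothing about
the model changes with larger runs.

## Oracles and the cost of the approximation

The package carries its own ground truth. `exact_posterior()` enumerates
all 96 joint states; `brute_force_G()` re-derives expected free energy
with no factorized shortcuts; `enumerate_policies()` counts (and lists)
action sequences, 8^5 = 32768 at depth five. `minimal_guaranteeing_depth()`
finds the smallest number of moves (samples plus the final choice) after
which the category is certain for every configuration. For open-loop
sampling sequences — the notion matching policies defined as fixed action
sequences, and hence the 8^5 enumeration — four quadrant samples are
necessary in the worst case, so five moves guarantee a correct
categorization. We note that *adaptive* strategies are strictly stronger
here: a decision tree needs only four moves (sample a quadrant; if it is
empty, sample the diagonally opposite quadrant; two empty diagonal cells
already imply "wait"), which `adaptive = TRUE` verifies by memoized
exhaustive search. The five-move figure should therefore be read as a
statement about open-loop policy spaces, not about the information
structure of the task.

## Known limitations

* **Phasic suppression.** With on-the-fly one-step policies that share
  their executed prefix, the precision update can only compare the
  executed candidate against the prior average, so `(pi - pi0) . G` is
  non-positive whenever the executed saccade was (tied-)optimal at
  planning time. The simulated dopamine trace therefore shows a flat
  (no-burst) response to uninformative null cues and clear bursts at
  informative ones, but not a strictly below-baseline dip at the null.
  A genuine dip would require either deep policies (distinct histories
  whose evidence can favor high-G alternatives) or a different functional
  form for the precision dynamics.
* **Wait scenes.** The factorized posterior cannot represent the
  context-reflection correlations that define wait scenes from sparse
  evidence; wait trials are slower and account for most residual errors.
  This is a property of the approximation being studied, not a defect to
  be tuned away.
* **Phantom epistemic value.** Because predictive outcome distributions
  are built from the product of marginals, a location whose content is
  pinned *jointly* but not *marginally* can still look informative, and
  symmetric two-scene ambiguities (e.g. a seed observed first) leave all
  quadrants near-tied. The stochastic action mode resolves these ties by
  sampling; the deterministic mode resolves them by index and can
  revisit.
* The scheme is calibrated to this 2x2 task; larger grids, probabilistic
  cue-category relations, and task-irrelevant distractors are out of
  scope, as is any learning of the likelihood or transition arrays.
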