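---
title: "Delayed Boolean networks: model, estimation, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delayed Boolean networks: model, estimation, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(booldelay)
```

## The model

A delayed Boolean network is a directed graph *G = {V, E}* over species
*x₁ … x_N ∈ {0, 1}*. Each edge *j → i* carries two integer dynamic
parameters and a small state machine (its *gate*):

- **Delayed activation θᵢⱼ ≥ 1** (minutes). The gate's input condition
  *h* is 1 exactly when the source has been on for at least θ
  *consecutive* minutes. Any interruption resets the run.
- **Sustained response rᵢⱼ ≥ 1**. While *h = 1* the gate emits 1 and an
  accumulator grows by *r − 1* per minute; when *h* drops the gate keeps
  emitting 1 while the accumulator drains by 1 per minute. A brief
  input therefore outlasts itself briefly, a long input for longer.
- **Delayed response rᵢⱼ ≤ −1**. The gate emits 1 only once *h* has
  held for a further |r| minutes; progress resets when the input drops.

A node's transfer function is an AND/OR/NOT tree over its gates' bits
(OR: either upstream activator suffices; AND: synergy; NOT: inhibition
or competition). Dynamics are fully synchronous at 1-minute steps: at
minute *t* every gate is updated from the minute-(t−1) node states,
then every rule is evaluated on the gate bits. Exogenous stimuli are
OR'd onto their node over half-open intervals `[start, end)`; an
in-silico knockout clamps a node to 0 for the whole run.

### The two accumulator readings

The published update pseudocode for the sustained branch reads
`tau <- tau + r - 1` *per on-minute*, with no cap — the sustain is then
an earned reservoir proportional to how long the input was active. An
alternative reading caps the accumulator at *r − 1*, making the sustain
a fixed duration. Both are implemented
(`accumulator = "accumulate"` / `"bounded"` in `simulate_network()`),
and the choice matters for the bundled model:

- With the **bounded** accumulator, no 45-minute stimulation ever keeps
  NF-κB on for the 107 consecutive minutes its A20 edge requires, so
  deleting A20 changes nothing — contradicting the model's central
  negative-regulator behaviour.
- With the **literal unbounded** accumulator, all the documented
  knockout contrasts hold: A20 deletion prolongs TNF-induced IKK
  activity and adds late NF-κB episodes, LPS responses are identical
  with and without A20, and IκBα deletion prolongs total IKK activity
  under both stimuli (via the IL-1 feedback, which bypasses A20).

The package therefore defaults to the literal reading. The acceptance
suite records where *neither* reading reproduces the published onset
and offset minutes of the acute IKK episode (5 and 60) or the chronic
secondary onset (≈ 6 h): the shortest TNF→IKK path has three θ = 1
edges, which pins the onset at minute 3 under any uniform per-edge
semantics, and the computed values are 3/125/8 h (literal) or 3/50/2 h
(bounded). We take this as evidence that the printed parameter table
and the printed update rule cannot jointly reproduce the printed
simulation panels — the transfer-function equations themselves are not
printed — and we report the computed values rather than force agreement.

### Initial condition

All nodes start off by default. Note that an all-off start is *not* a
fixed point of the bundled model: the IκBα rule (NOT IKK-gate OR
NF-κB-gate) evaluates to 1 on a quiet network, so IκBα rises at minute
1 — biologically correct, since resting cells hold NF-κB inactive
through IκBα — and NF-κB shows a single-minute start-up blip. Passing
`initial = c(IkBa = 1)` starts from the true resting state and removes
the blip; the parameter-recovery study does this.

## Structural analysis

`simplify_network()` collapses linear relay chains: any non-stimulus,
non-observable node with one input and one output is removed and the
two edges fused, with θ composing additively, the fused sustain taken
from the *receiving* edge (sustain is a property of the downstream
reaction; only the topology reduction itself is prescribed), and signs
multiplying. Two deliberate protections:

- nodes on directed cycles are preserved. Feedback effectors are
  dynamical units in their own right, and the knockout interface needs
  them as nodes; without this rule A20 (one input, one output) would be
  fused into a composed NF-κB → TNFR1 inhibition and the bundled model
  would not be a reduction fixed point.
- a collapse that would create a duplicate edge between an existing
  pair is skipped.

Onset times are invariant under the reduction (delays add), but each
removed node contributes one minute of trailing activity — node states
lag their gates by one synchronous step — so the off-transition of the
full chain lags the collapsed one by the number of removed nodes. The
test suite asserts exactly this relationship.

`find_kernel()` returns the nodes on *every* directed simple path from
the stimulus entry points to a read-out — for the bundled model, the
IKK–IκBα–NF-κB core. `feedback_regulators()` enumerates a hub's direct
targets that sit on a cycle of length ≥ 3 back to the hub; the mutual
NF-κB ⇄ IκBα pair is its own self-regulatory loop and is excluded by
default (configurable), which yields the three feedback routes TNF,
A20, IL-1.

## Binarization

Continuous lane profiles (`node, t, value`) are binarized by per-lane
background subtraction (minimum subtraction, floored at 0) followed by
Kapur maximum-entropy thresholding: over a histogram of the min-max
normalized values, choose the split maximizing the summed Shannon
entropies of the two classes (0·log 0 = 0; ties toward the lower
threshold by default). The criterion is invariant under positive affine
rescaling. The implementation is checked bin-by-bin against an
exhaustive-scan oracle.

Practical limits, worth knowing:

- **Bin count must match lane length.** With few samples per bin the
  entropy sum degenerates to log k + log(n − k) and simply balances
  counts, splitting the larger cluster. The default 256 bins suits
  dense lanes (≈ 50+ samples); for a 10–20-sample lane use `bins` of
  about 6–16.
- **Both states must be represented.** A lane that is ON for 95% of its
  samples gives the threshold almost nothing to separate, and the
  estimate is unreliable. At a signal-to-noise ratio of 5 (level
  separation / noise sd), balanced lanes binarize with ≥ 95% bit
  accuracy; strongly imbalanced short lanes do not.
- **Keep the background away from zero.** Clipping intensities at 0
  piles probability into the first bin and drags the threshold into the
  foreground. The synthetic generator defaults (background 100, signal
  200, sd 20, arbitrary densitometry units) keep the background five
  standard deviations above zero, as integrated lane densities are.

## Genetic-algorithm fitting

Free edges are encoded as an integer chromosome of interleaved (θ, r)
genes in the network's declared edge order. Fitness is the mean squared
error between simulated and observed bits over all (experiment, node,
timepoint) triples — 0 iff every sampled bit matches. Operators follow
the published configuration: roulette-wheel selection with weight
1/(MSE + ε), ε = 10⁻⁶; single-point crossover at a uniform cut, applied
with probability 1 by default; per-gene mutation (2%) resampling
uniformly within the gene's range; elitism; a fixed number of
generations (defaults: population 1000, 800 generations). Runs are
deterministic given `seed`, and the best-so-far history is
non-increasing by the elitism guarantee.

`two_stage_fit()` implements kernel-first training: stage 1 fits only
the edges among the kernel nodes, with every other edge pinned at
(θ = 1, r = 1), against wild-type data; stage 2 freezes the kernel at
its stage-1 values and fits the remaining edges against the extended
set (wild type plus knockout conditions).

## The parameter-recovery study

The validation study (shared by the test suite and described here as
the package's own design) asks: can the two-stage GA, at a reduced
budget of population 150 × 200 generations, exactly refit a known
ground truth from binarized synthetic densitometry? The design:

- **Truth**: the bundled network's topology with synthetic, exercisable
  parameters (`synthetic_nfkb_truth()`): all non-kernel edges at
  (1, 1) — making stage 1's pinning assumption consistent with the
  generating model — and kernel values IKK→IκBα (30, 2), IκBα→NF-κB
  (1, 1), NF-κB→IκBα (300, −62). The last never fires within any
  training run, exactly as the bundled model's printed resynthesis
  term (θ = 96, r = −62, requiring a 158-minute NF-κB run) never fires
  at feasible horizons.
- **Conditions**: 45-min TNF and 45-min LPS wild type (stage 1), plus
  45-min TNF with A20 knocked out (stage 2); horizon 60 min; start from
  the resting state; all ten regulated nodes observed every 3 minutes;
  intensities binarized through the standard pipeline (noiseless for
  the headline study; signal-to-noise 10 with bin count 6 for the noisy
  variant).
- **Search**: sustained responses only, r ∈ [1, 3] (with step-like
  training signals a delayed response is indistinguishable from a
  longer activation delay — θ + |r| compensation — so the delayed
  branch only adds aliases), θ ∈ [1, 40], elitism 10, three fixed
  restarts (seeds 1–3), best restart reported. The restarts compensate
  a 27-fold budget reduction against the reference configuration.
- **Scores**: the best restart must reach MSE = 0, and at least 80% of
  the *identifiable* delays must be recovered within ±2 minutes.
  A delay is identifiable when perturbing it alone by ±3 minutes (both
  feasible directions) changes the sampled training bits. The 3-minute
  observation grid makes the unavoidable sampling-alias window ±2
  minutes, matching the recovery tolerance.

Under this design all three restarts reach exact zero error and recover
all 15 identifiable delays; with signal-to-noise 10 every restart still
recovers ≥ 80%. What the study does *not* show: recovery of the
bundled model's printed parameter values (several are structurally
unexercisable at feasible horizons, and the fast rest-pinned feedback
loops make that landscape an oscillator-phase needle-in-a-haystack at
this budget), and robustness to strongly imbalanced or very short noisy
lanes, where the thresholding itself is the weak link (above).

## Numerical and interface choices

- Time is discrete minutes; t = 0 is the first simulated minute;
  stimulus intervals are half-open.
- Edge order (rules in declaration order, terms in rule order) defines
  chromosome layout; serialization round-trips are exact.
- The compiled simulator (Rcpp) is validated bit-for-bit against a
  literal pure-R transcription of the update rules on random networks;
  the two are written independently.
- Degenerate inputs fail loudly: zero r, non-positive lags, unknown
  nodes, a knockout of a protocol-driven stimulus node, constant lanes
  (no threshold exists), empty training sets.
- `ga_config()` ranges default to θ ∈ [1, 400], r ∈ [−100, 100] \ {0},
  generously covering the bundled model's printed extremes (373, −62);
  studies should narrow them to the dynamics their data can exercise.

## Known limitations

- Boolean levels only: stimulus *strength* is not representable, only
  timing and duration.
- Synchronous deterministic updates; no asynchronous or stochastic
  schemes, no ODE approximation.
- The published acute window (minutes 5–60) and chronic secondary onset
  (≈ 6 h) of the bundled model are not reproduced by any reading of the
  printed rules we could construct (computed: onset 3; offset 125
  literal / 50 bounded; secondary 8 h literal / 2 h bounded). The
  package reports what the printed model actually does.
- A 45-minute LPS stimulus is shorter than the bundled model's shortest
  LPS delay (θ = 87), so it produces no response at all; LPS-driven
  behaviour needs sustained stimulation (e.g. 180 min).
- Maximum-entropy binarization needs balanced, adequately sampled
  lanes; see above.
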