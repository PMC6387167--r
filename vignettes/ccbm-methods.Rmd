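---
title: "Causal behaviour models for activity and goal recognition: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causal behaviour models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ccbm)
```

This vignette explains the model the package implements, the tunable
parameters that matter, what the synthetic data generator does and does not
emulate, and the design decisions taken where the design was genuinely open.
It states no empirical result that the test suite or the acceptance script
does not itself compute.

## 1. The model

### 1.1 Symbolic layer

A behaviour model is written in a small PDDL-like dialect: a type forest
rooted at `object`, typed objects, predicate schemas, and action templates
with `:parameters`, `:precondition` (conjunctions of possibly negated atoms
plus `(= ?x ?y)` equality atoms), `:effect` (add/delete atoms), `:duration`
and `:observation` clauses. Grounding substitutes all type-compatible
objects, deterministically (template declaration order, then lexicographic
arguments), yielding the action set *A* and predicate set *P*; a world state
is a truth assignment over *P*. The dialect is deliberately closed: no
conditional effects, numeric fluents or quantifiers. Where one effect both
adds and deletes an atom, delete applies first and the add wins — the common
PDDL convention, fixed here because the grammar's source material shows only
fragments.

Plan enumeration (`enumerate_plans`) performs a depth-first search over
action sequences from the initial state. Two closure rules keep the plan
library finite and well-defined: actions whose effect leaves the state
unchanged (notably the always-applicable `unknown` action) are excluded from
plans by default, and a branch stops at its first goal hit, so the library
is prefix-free. Both rules are configuration, not hard-coded.

### 1.2 Probabilistic layer

The filter state is the tuple (action A, termination flag D, goal G, world
state S, start time U). The five sub-models follow the structure described
in the README; two points deserve emphasis.

**The duration hazard is implemented exactly as printed in its source**,
with denominator 1 − F(vₜ):
termination probability = (F(vₜ) − F(vₜ₋₁)) / (1 − F(vₜ)), clipped to
[0, 1], with F(vₜ) → 1 treated as certain termination. This differs from
the textbook discrete hazard, whose denominator is 1 − F(vₜ₋₁); that form
is available as `hazard_mode = "standard"` in `selection_params()`. For a
geometric duration with parameter p the printed form gives the constant
p/(1 − p) and the standard form gives p — both memoryless, which the test
suite checks. Normal durations are truncated at zero (durations are
positive); empirical durations use the sample CDF of annotation
inter-label gaps.

**Action selection** is a softmax over the applicable actions with features
evaluated on each candidate's successor state: f₁ = −(exact goal distance by
BFS on the reachable state graph), f₂ = −(count of unsatisfied goal atoms).
When no state graph is supplied, f₁ falls back to f₂ (the landmark surrogate
*is* the distance estimate); when the goal is unreachable from a successor,
f₁ falls back to f₂ minus a large constant (default 100) rather than −∞, so
deviations from the optimal sequence always remain possible. The weights
default to λ₁ = λ₂ = 1 in `selection_params()`; no canonical values exist,
and the monotone effect of λ₁ is property-tested instead.

Time is the discrete window index produced by preprocessing; the clock V is
treated as observed input. The unbounded start time U is collapsed to the
elapsed time e = V − U with a configurable cap (`elapsed_cap`, default 30
steps): beyond the cap the hazard is evaluated at the cap. When every
duration in the model is geometric the hazard is constant in e and the cap
degenerates to 1 — the exact filter detects this and collapses the
dimension.

### 1.3 Observations

P(Y|X) factorises into an action term and an environment term. The learned
model emits only action-class distributions, so P(W|S) defaults to 1 and a
hook accepts user-supplied environment likelihoods. The classifier is a
hand-written CART: Gini criterion, thresholds at midpoints of consecutive
distinct sorted feature values, ties broken by feature column order then
smallest threshold, leaves smoothed with add-one Laplace over the full
class set. All split statistics are computed from integer class counts, so
training is provably invariant to row permutation — a property the suite
asserts. A tree was hand-written because no tree learner is available in
the target environment; the determinism guarantee is the compensating
benefit. Hyperparameters (depth limit, minimum split size, smoothing α) are
exposed in `observation_spec()` with permissive defaults (no depth limit,
α = 1).

The optimistic protocol (OMo) trains on the full corpus it will be tested
on — an intentionally over-fitted upper reference. The pessimistic protocol
(OMp) trains on the first run only, the one constructed to contain all
action classes.

### 1.4 Inference

`exact_filter()` runs the forward recursion over the realised support of
(action, goal, world state, elapsed time), predicting with the structured
transition model and updating with the per-step class distribution. Support
states whose posterior weight falls below `prune` (default 1e-12) are
dropped and the rest renormalised; the threshold sits three orders of
magnitude below the filter's verification tolerance (1e-9 against the
brute-force trajectory oracle) while keeping the support tractable. Setting
`prune = 0` restores the fully exact recursion, which is what the oracle
tests use. If the support exceeds `max_support` the filter aborts with a
typed condition that recommends the particle filter.

`particle_filter()` is sequential importance resampling with systematic
resampling when the effective sample size falls below half the particle
count. Degenerate updates (all weights zero) raise an error naming the
step in both filters.

Goal-recognition read-outs operationalise two deliberately under-specified
notions. "Recognised at least once" means: the goal was the per-step
posterior mode at one or more steps (`multigoal_estimate`); a mass-threshold
alternative would be easy to add but the mode rule is the default.
"Converged to the correct goal" means: the posterior mode at the final step
equals the true composite goal and has held for the last k steps
(`pooled_goal_recognised`, k = 1 by default).

### 1.5 HMM baselines

Transition matrices are estimated by counting label bigrams — no
Baum–Welch. A class observed only at the end of every training sequence has
an empty transition row; it receives a self-loop of 1, a documented rule the
data source leaves open. Priors are occurrence frequencies. The joint HMM
for goal recognition concatenates per-goal sub-models (trained on the runs
containing that goal, so sub-models may have different state subsets) behind
a common start state whose outgoing mass is the goal prior times each
sub-model's normalised state prior; the goal posterior is block
marginalisation of the forward filter.

## 2. Preprocessing

Raw records (timestamp, sensor, value) are deduplicated (identical
duplicates merge; conflicting values at one timestamp keep the last record,
with a warning), forward-filled (undefined cells take the nearest previous
value; leading cells take a declared per-sensor default, 0 unless
overridden), and windowed. For window size w and overlap fraction ov the
step is max(1, ⌊w·(1 − ov)⌋) — 2 rows for the default w = 5 at 50% — and
each full window is summarised per sensor by max (a mean mode exists; max is
the default for binary and continuous channels alike, following the
pipeline's blanket rule). Annotation labels attach to windows by majority
dwell time within the window's raw span, ties going to the earliest-starting
label; spans before the first label are `"(unknown)"`. Window counts for
odd w and the labelling rule are package decisions — the source pipeline
states neither.

## 3. The synthetic kitchen

`build_kitchen_problem()` instantiates the cooking ontology — actions
move/get/put/prepare/eat/drink/clean/unknown over locations {kitchen,
study}, items {ingredients, tools} and a configurable meal list — and one
named goal per meal (*meal consumed, kitchen cleaned*). Multi-meal runs use
composite conjunction goals (e.g. `coffee+pasta`). Pooled health goals
(healthy/unhealthy × meal/drink) are *not* separate symbolic goals: a
conjunction-only goal language cannot express "some healthy meal", so the
health target is realised by summing posterior mass over the meal goals in
each pool (`pool_posterior()`), which is exactly the block marginalisation
the probabilistic semantics licenses.

The generator simulates the model's own dynamics forward until the goal
set holds, then emits sensor readings per raw tick: each action class
activates its characteristic binary channels (get → fridge/cupboard,
clean → water flow, drink → kettle, move → movement, put → drawers,
eat → sink cupboard) with probability 1 − noise, and every inactive channel
fires with probability noise; temperature and humidity are continuous with
a prepare-driven shift and noise-scaled jitter. At noise 0 the emission is
deterministic and injective in the class; at noise 0.5 binary channels are
exactly uninformative. The default noise is 0.05.

Three generator choices are worth recording:

- **Goal-directedness.** The simulated actor uses λ₁ = 3, λ₂ = 1. With
  λ₁ = 1 the softmax over ~10 applicable actions picks a distance-reducing
  action only ~25% of the time, and simulated "coffee" runs routinely
  prepared and ate a full pasta meal first — behaviour the emulated corpus
  never shows (its runs execute roughly twice the minimal plan length, for
  their own meals). λ₁ = 3 puts the optimal-action share near 50–60%,
  matching that deviation rate. This is a statement about the simulated
  *actor*; the recogniser's default weights stay at 1.
- **The first run is exploratory.** The emulated corpus' first run is by
  far its longest and the only one containing all action classes, and it is
  the designated training run of the pessimistic protocol. `generate_corpus`
  therefore simulates run 1 with the softer weights (λ₁ = 1) and reseeds it
  (bounded, deterministically) until all eight classes occur.
- **Durations are geometric** (mean 2.5–3.3 steps by class). This keeps the
  semi-Markov layer honest (the hazard machinery is exercised and tested
  with non-memoryless families elsewhere) while collapsing the elapsed-time
  dimension of the exact filter, which is what makes exhaustive filtering of
  whole corpora affordable in the tests.

What a green test does and does not establish: the generator shares its
transition dynamics with the recogniser, so recovery results certify the
inference machinery (the Bayes loop closes), not robustness to model
mismatch; emissions are conditionally independent given the class, with no
sensor drift, latency or missingness; and class-level emissions mean two
meals of the same consumption type are distinguishable only through the
action-selection preference, not through the sensors.

## 4. Numerical and degenerate-input choices

- Softmax scores are max-shifted before exponentiation (shift invariance is
  property-tested).
- `decode_actions` breaks class ties alphabetically; goal modes likewise.
- Filter marginals are renormalised every step; a zero-mass update is an
  error, not a silent NaN.
- The state-space closure aborts at `max_states` (default 1e6) with a typed
  condition carrying the partial graph and frontier.
- Empty transition rows, empty feature subsets (evaluated as the
  majority-class predictor and included in the 2ⁿ count), and all-tied
  Wilcoxon pairs (statistic 0, p = 1) all have documented, tested rules.
- Best-feature-subset ties: highest accuracy, then smallest subset, then
  lexicographic order.

## 5. Known limitations

Exact filtering is feasible only for small worlds (a few hundred reachable
states with memoryless durations); larger models must use the particle
filter. Goals are conjunctions of literals — disjunctive targets are
handled at the read-out level, not in the goal language. The specialised
HMM is trained on the test run's own annotation (the wiring the comparison
design implies), which makes that baseline partially circular by
construction; both wirings are possible via `estimate_transitions`
directly. Observation models treat all ground actions of a class
identically — per-action observation hooks are representable through the
`:observation` clause but unused by default.
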