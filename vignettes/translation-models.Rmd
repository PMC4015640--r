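---
title: "Codon-based models of mRNA translation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon-based models of mRNA translation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribotraffic)
```

This vignette documents the models implemented in **ribotraffic**, the
assumptions behind each, and every numerical and design choice a user
or maintainer might want to interrogate.

## 1. The codon-based lattice model

Translation is modelled as unidirectional traffic of hard-core
particles (ribosomes) on a lattice of `n` codons.  A ribosome covers a
footprint of `r` consecutive codons; its position is identified with
its *head* (the rightmost covered codon).  Three event types, indexed
by the head position at which they occur, drive the dynamics:

| event | index | rate | occurrence condition | effect |
|---|---|---|---|---|
| entry | 0 | `alpha` | codons `1..r` empty | fill `1..r` |
| hop | `i = r..n-1` | `gamma[i]` | codon `i` occupied, `i+1` empty | free `i-r+1`, fill `i+1` |
| exit | `n` | `beta` | codon `n` occupied | free `n-r+1..n` |

All rates are dimensionless inverse times (events per unit time); only
their ratios matter to the stationary state, and the reported
translation rate `c` inherits the same unit.  The event set has
`n - r + 2` members.  The occurrence conditions above are the full
window predicates; on reachable states the entry and exit conditions
reduce to single-codon tests (codon `r` empty, codon `n` occupied)
because a reachable state cannot have a partially filled entry or exit
window.  The package uses the reduced predicates internally and keeps
the full-window forms available (`allowed_events(..., reduced =
FALSE)`); their equivalence over the entire reachable set is asserted
in the test suite.

**Reachable states.** Occupied codons always decompose into disjoint
runs of exactly `r` consecutive ones, so the state count is
`sum_k choose(n - k*r + k, k)` over ribosome counts `k` — for `r = 1`
all `2^n` vectors, for `n = 50, r = 12` just 1113.
`enumerate_states()` generates them in a canonical order: ribosome
count descending, then lexicographically by ascending head-position
tuples.  *This order is a package convention*, chosen because it makes
the 4-state toy matrix directly readable (`[1 1], [1 0], [0 1],
[0 0]`); nothing in the field fixes an order for larger lattices.

**Assumptions inherited from the formalism.** Ribosomes are
indistinguishable (only occupancy matters); movement is strictly
unidirectional with hard-core exclusion; the free-ribosome pool is
infinite (initiation never depletes it); elongation at each codon is a
single memoryless step.  None of the solvers below relax these.

## 2. Update rules and the five simulators

The rate law alone does not fix the process: within a time step more
than one event may be possible, and the *update rule* decides how
simultaneity is resolved.  `simulate()` implements five schemes.

Four are **random-sequential** (one event at a time, no order imposed)
and are statistically equivalent at stationarity; they differ only in
efficiency and in how time is discretized:

* `rs_varying` — draw among the *currently allowed* events with
  probability `gamma_i / sum(allowed gamma)`; advance time by
  `1 / sum(allowed gamma)`.  Every step fires an event (no no-op
  steps); the time step varies with the state, in the manner of
  kinetic Monte Carlo.
* `conventional` — pick an index uniformly from the *full* event set
  (`1/(n-r+2)`), fire with probability `gamma_i` only if allowed;
  `dt = 1/(n-r+2)` always.
* `alternative` — select index `i` with probability
  `gamma_i/(n-r+2)`, no event with the residual probability; same
  fixed `dt`.
* `efficient_fixed` — select with probability `gamma_i / sum(gamma)`
  over the full set; `dt = 1 / sum(gamma)`.  Its selection
  probabilities are exactly the mixture weights of the exact solver's
  transition matrix, and `I + Q/sum(gamma)` is the uniformization of
  the continuous-time chain, which is why this scheme is the bridge
  between simulation and the exact solver.  Among fixed-step schemes
  it has the smallest no-op fraction (`1 - sum_i p_i psi_bar_i`).

The `conventional` and `alternative` schemes interpret rates as
probabilities, so when `max(gamma) > 1` all rates are rescaled by the
maximum and the reported times un-scaled afterwards; the other schemes
need no rescaling.

The **parallel** rule (`parallel`) fires *all* currently allowed
events in one step, each independently with probability
`gamma_i / max(allowed gamma)`, and advances time by
`1 / max(allowed gamma)`.  For unidirectional hops this is equivalent
to a left-to-right particle-ordered sweep: a firing on the left cannot
enable or disable an event to its right within the step, so the
package freezes the allowed set at the start of the sweep and fires
left to right.  The parallel rule is not a numerical variant of the
random-sequential one — it is a different model, and it produces
systematically faster translation (its steady state weights states
that allow many simultaneous events more heavily).  The test suite
asserts the rate inequality on bottleneck scenarios and, at the
full `n = 50, r = 12` geometry, the accompanying depletion of the
first codon.  That depletion is footprint- and parameter-dependent:
on a reduced `n = 20, r = 4` lattice at high initiation it reverses,
which is why the test pins it at the full geometry.

**Estimators.** All summaries are time-weighted: each visited state is
weighted by the `dt` of its step.  Per-step averaging would be biased
for `rs_varying` (steps are shorter in busy states) and would make the
schemes incomparable.  The translation-rate estimator is exit count
over simulated time after burn-in.  Burn-in defaults to 10% of the
steps — the sources this package follows never state an equilibration
convention, so this is a package choice, configurable per run.

**Reproducibility.** One RNG stream per run, seeded from `seed`; draws
are consumed in a fixed documented order (selection draw, then firing
draw; one uniform per allowed event in sweep order for `parallel`).
Identical seed and configuration give bit-identical runs; the suite
asserts this for every scheme.

## 3. The exact stationary solver

Each event defines a Boolean update rule on the occupancy vector: the
event's transformation where its condition holds, the identity
elsewhere.  Writing each rule as a 0/1 column-stochastic matrix `M_i`
over the reachable states (exactly one entry per column) and averaging
with the selection probabilities `p_i = gamma_i / sum(gamma)` gives
the transition matrix `M_E = sum_i p_i M_i` of a finite Markov chain —
irreducible and aperiodic whenever all rates are positive.  Its
stationary vector is solved and converted to codon densities
`rho = sum_i pi_i chi_i` and translation rate `c = beta * rho_n`.

Design and numerical choices:

* **Reachable-set construction, not a 2^n embedding.**  The matrices
  are built directly over the reachable states.  A semi-tensor-product
  embedding over all `2^n` Boolean states followed by row/column
  deletion yields the same reduced matrix but is exponentially
  wasteful; the direct construction is validated by exhaustive
  agreement between the Boolean rules and the predicate-plus-apply
  semantics in the tests.
* **Restriction to the empty-lattice component.**  Before solving, the
  state set is restricted (breadth-first) to states reachable from the
  empty lattice under events of strictly positive rate.  With all
  rates positive this is the full set; with degenerate profiles
  (`alpha = 0`, or a premature stop with `mu = 0`) it is the closed
  set the dynamics actually lives on, and the solver returns the
  correct absorbing answer (`c = 0`, downstream densities 0) instead
  of failing on a reducible chain.  A chain that is still singular
  beyond the rank-one deficiency raises a diagnostic error.
* **Linear solve first, power iteration as cross-check.**  The default
  solves `(M_E - I) pi = 0` sparsely (Matrix) with the normalization
  `sum(pi) = 1` replacing one equation — deterministic and exact to
  machine precision (the toy model reproduces the printed 4-decimal
  values to 1e-12).  `method = "power"` iterates `M_E^t` with relative
  tolerance 1e-12 and a 1e5 iteration cap, mirroring the limit
  definition; the suite checks both agree.  Residual `|M_E pi - pi|`
  above 1e-8 warns; negative components below -1e-8 error, smaller
  ones are clipped and renormalized.
* **Sensitivities without noise.** `rate_sensitivity()` is a central
  finite difference of two exact solves (default `delta = 1e-4`,
  rejected if it would make a rate non-positive).  This is the use
  case where exactness matters most: Monte-Carlo error of order 1e-3
  swamps small sensitivities.

The suite validates the solver against an independently written
continuous-time master-equation oracle (generator assembled from the
raw rates over a brute-force enumeration) on randomized small
instances, including premature-stop models, to 1e-9.

## 4. The mean-field (Heinrich–Rapoport) model

The mean-field model tracks head-occupancy probabilities `h_i`
(`i = r..n`) and closes the correlation hierarchy with conditional
vacancy probabilities:

* `W_0 = 1 - sum_{s=r}^{min(2r-1,n)} h_s` (entry window free),
* `W_i = (1 - sum_{s=1}^{r} h_{i+s}) / (1 - sum_{s=1}^{r-1} h_{i+s})`
  for `r <= i <= n-r`, `W_i = 1` beyond,

with fluxes `c_0 = alpha rho_m rho_r W_0`, `c_i = gamma_i rho_m h_i
W_i`, `c_n = beta rho_m h_n`.  `rho_r` (free-ribosome concentration)
is held at 1 by default — no pool depletion — and `rho_m` only scales
time.

* **Transient integration** (`mf_integrate`): `rho_m dh_i/dt =
  c_{i-1} - c_i` via `deSolve::ode` (lsoda, default tolerances), from
  the empty profile unless given.
* **Steady state** (`mf_steady_state`): at stationarity all fluxes
  equal `c`, which closes the system into one scalar unknown: given a
  trial `c`, `h_i = c/gamma_i` on the last `r` codons, a backward
  recursion fills the rest, and the entry relation yields an implied
  initiation rate.  `implied_alpha(c)` is monotone increasing on the
  physical branch (asserted numerically in the tests), so the root of
  `implied_alpha(c) = alpha` is found by bisection on
  `(0, min(gamma) (1 - 1e-12))` to relative tolerance 1e-13; trial
  values producing `h` outside `[0, 1]` or a non-positive vacancy
  denominator are rejected as too large, which automatically selects
  the smallest physical root (the low-density branch reached from an
  empty start).  If even the bounding `c` implies less initiation than
  requested, the solver warns and returns the bound (initiation is not
  rate-limiting there).

The two solvers agree to 1e-8 (vector max-difference) on the test
scenarios, and the `alpha -> 0` limit recovers `c -> alpha` within 1%
at `alpha = 1e-3 gamma`.  Mean-field closure error against the exact
solver is a few percent at slow initiation and grows with crowding;
the suite records the comparison as an inequality-free tolerance
check at slow initiation only, because the deviation at fast
initiation is a genuine property of the approximation, not a bug.

## 5. The deterministic timed Petri net

Replacing each event's stochastic rate by a deterministic waiting time
`1/gamma_i` turns the model into a timed Petri net whose steady
translation rate is set by the slowest waiting time:
`c = 1/max(w_init, max_i 1/gamma_i, 1/beta)`.

* **Initiation window.**  With a footprint, initiation waits both on
  its own clock and on the previous ribosome clearing the first `r`
  codons.  The phrase "the initiation rate and the sum of the first
  `r` elongation rates, whichever is slower" admits two readings; the
  default is `w_init = max(1/alpha, sum_{j=r}^{2r-1} 1/gamma_j)` (sum
  of waiting times — the traversal time of the entry window), with
  `init_window = "sum_of_rates"` giving
  `max(1/alpha, 1/sum(gamma_j))`.  Neither is asserted as canonical.
* **Premature stop.**  Three-way branching has no waiting-time
  semantics, so the stop codon enters only as a slowdown:
  `w_j = 1/(mu gamma_j)`; `mu = 0` gives an infinite wait and `c = 0`.
* **Simulator.**  `petri_simulate()` runs the event-driven schedule:
  ribosome `m` arrives at head `i+1` at `max(arrival(i) + w_i,
  release of codon i+1 by ribosome m-1)`; entry fires at
  `max(previous entry + 1/alpha, window free)` — a clock with memory,
  which makes the asymptotic exit rate match the closed form in the
  regimes the closed form describes.  Codon densities are occupied
  time fractions over the second half of the horizon (the periodic
  regime); this readout is a package convention, as the deterministic
  model has no canonical density definition.
* **A genuine refinement the closed form misses.**  With `r > 1`, a
  ribosome queued behind a mid-lattice slow codon must re-traverse
  `r - 1` codons before reloading the bottleneck, so the schedule's
  true period there is `(r-1)/gamma + 1/gamma_slow`, slower than the
  slowest-waiting-time value.  The closed form — which is what makes
  one and two consecutive slow codons indistinguishable, the model's
  characteristic limitation — is kept as the package's headline Petri
  rate; the schedule's requeueing period is asserted separately in the
  tests.  Users comparing `petri_simulate()` to
  `petri_translation_rate()` on footprint models with internal
  bottlenecks should expect this difference.

## 6. Regulation

**Slow codons** are plain rate edits (`with_slow_codons()` or the
`slow_codons` constructor block) and flow through every solver.  The
exact solver, the stochastic simulators and the mean-field model all
show two consecutive slow codons slower than one at matched rates; the
Petri closed form cannot (see above).

**Premature stop codon.**  At position `j` the hop splits into
readthrough (rate `mu * gamma_j`, a normal hop) and premature
dissociation (rate `(1-mu) * gamma_j`, clearing codons `j-r+1..j`) —
the only split that keeps the total attempt rate at `gamma_j` while
making readthrough a fixed per-attempt probability `mu`.  The
dissociation event integrates into the event table, all simulators and
the exact solver (one extra event matrix).  At stationarity the
single-flux balance splits at `j`: upstream flux = readthrough +
dissociation flux, downstream flux = readthrough flux = `c`.  The
full-length output `c` remains `beta * rho_n`.

**Initiation autoregulation.**  `alpha = alpha_I / (1 + k_I rho_I)`
with `d rho_I/dt = c rho_m - d_I rho_I`.  Two couplings:

* `feedback_fixed_point()` iterates `rho_I <- (1-d) rho_I + d * c(alpha)
  rho_m/d_I`, `alpha <- alpha_I/(1+k_I rho_I)` with damping `d = 0.5`
  (a guard against oscillation; the map is typically already
  contracting) until successive `rho_I` differ by at most `tol`
  (default 1e-10; floored at 1e-4 for the simulation backend, the
  Monte-Carlo noise floor).  Any steady-state backend can supply
  `c(alpha)`; the exact solver is the recommended one because the
  iteration then has no sampling noise.
* `simulate()` with a feedback block couples the protein stochastically
  to the varying-step random-sequential run: every step, `rho_I`
  decays by the exact factor `exp(-d_I dt)` and each completed exit
  adds `rho_m`; `alpha` is recomputed before the next draw.  The exact
  decay factor matters: a first-order factor `1 - d_I dt` at this
  chain's step sizes (`dt` up to 1) systematically underestimates
  `rho_I` and breaks the ergodic identity `E[rho_I] = c rho_m / d_I`,
  which the exact factor satisfies pathwise up to an `O(1/T)` boundary
  term — the suite asserts it to `5/T`.  An all-deterministic
  alternative (`feedback_scheme = "euler"`, increment
  `(c_hat rho_m - d_I rho_I) dt` with the running rate estimate) is
  kept for comparison; neither scheme is claimed canonical, as the
  discretization is an open choice.  The reported `rho_I` average is
  time-weighted (exact within-step integrals), since per-step
  averaging is biased by the state-dependent step length.

The two couplings agree on `(c, rho_I)` to within the tolerance the
suite asserts (10% relative on a small lattice, dominated by
Monte-Carlo error and genuine fluctuation effects: protein jumps of
size `rho_m` are not small relative to the mean, so exact coincidence
is not expected).  Monotonicities — `c*` decreasing in `k_I`,
increasing in `d_I`, `rho_I* = c* rho_m/d_I` — are asserted through
the exact backend.

## 7. Scenario presets and what they (do not) emulate

`scenario()` bundles the parameter sets used throughout: the
two-codon toy lattice (`alpha = 0.6, beta = 0.4, gamma = 1`) whose
exact solution is printed in the README; initiation sweeps at
`n = 50, r = 12` with `beta = gamma = 0.5` (formalism comparison) and
`beta = 0.5, gamma = 1` (update-rule comparison); slow codons at
position 25 (single) or 25–26 (consecutive, equal rate) with
`alpha = beta = 1`; a premature stop at codon 25 with
`alpha = 1, beta = 0.1`; and initiation feedback with
`beta = gamma = rho_m = 1`.  The maximum initiation rate of the
feedback preset is not published; `alpha_I = 1` is this package's
default and is an explicit argument.  The lattice geometry
`n = 50, r = 12` follows the standard illustrative choice for these
models.

These are *synthetic scenarios*, not data: they exercise the
formalisms' qualitative disagreements (update-rule effects, bottleneck
interactions, feedback) under clean rate profiles.  Real transcripts
have heterogeneous codon-specific elongation rates, finite ribosome
pools, co-translational events and mRNA turnover, none of which the
presets represent; passing the suite shows the solvers implement their
models correctly, not that any model fits a particular biological
dataset.

Preset runs default to reduced step counts (4000) so they stay
desk-scale; `full = TRUE` switches to 200 000 steps.  The test suite
runs stochastic checks on reduced lattices (`n <= 20, r <= 4`, up to
~1.2e5 steps) and the exact solver at the full 1113-state geometry;
these sizes are the package's chosen balance between statistical
resolution and a test suite that stays fast enough to run routinely.

## 8. Degenerate inputs and edge cases

* `alpha = 0` (or `alpha_I = 0`): the empty lattice is absorbing.
  Simulators return a summary flagged `degenerate`; the exact solver
  returns the point mass on the empty state and `c = 0`.
* A zero hop rate or `mu = 0` partitions the lattice: the exact solver
  solves on the closed component containing the empty state
  (downstream densities 0); simulators simply never fire the event.
* `n = r`: no hop events; the event set is `{entry, exit}`.
* `beta` must be positive (the translation-rate readout `c = beta
  rho_n` is otherwise meaningless); all other rates may be zero.
* Ties in `rank_states()` break by canonical state order.

## 9. Known limitations

* No finite ribosome or tRNA pools; initiation pressure is constant.
* The exact solver's state space grows near-exponentially in `n/r`;
  it is practical to a few thousand states (seconds), not for
  hundred-fold larger lattices.  Iterative eigensolvers would extend
  it; not implemented.
* No exact solver for the parallel update rule — only simulation.
  The parallel rule's stationary law is not the uniformized chain of
  the rate matrix.
* The Petri-net comparator deliberately stays deterministic; premature
  stops enter only as slowdowns, and its closed form ignores the
  footprint-requeueing effect described in section 5.
* The mean-field model excludes premature stop codons (the branch
  would need an additional early-termination flux, which its closure
  does not define).
* Transient (time-dependent) distributions are available only through
  simulation or power iteration, not as a solver product.
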