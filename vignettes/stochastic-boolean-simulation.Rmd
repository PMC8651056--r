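---
title: "Stochastic simulation of logical models as continuous-time Markov chains"
author: "boolctmc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic simulation of logical models as continuous-time Markov chains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boolctmc)
```

## The model

A logical model is a set of binary nodes with update rules. `boolctmc`
gives these rules continuous-time stochastic semantics: every node $i$ has
two propensity functions of the full state $S$, $\rho^{\uparrow}_i(S)$
(switch on, applies while $S_i = 0$) and $\rho^{\downarrow}_i(S)$ (switch
off, applies while $S_i = 1$). The state evolves as a Markov jump process:
with total propensity $R(S) = \sum_i r_i(S)$ the waiting time to the next
jump is Exponential($R$), and node $i$ flips with probability $r_i/R$ — the
Gillespie algorithm, applied to asynchronous Boolean dynamics. A state with
$R = 0$ is a fixed point and is held for the rest of the trajectory.
Separating activation from inactivation introduces physical time and lets
processes run on different time scales; a pure-logic model embeds with
$\rho^{\uparrow} = [\mathrm{logic}]\,k_{up}$,
$\rho^{\downarrow} = [\lnot\mathrm{logic}]\,k_{down}$
(`defaultRatesFromLogic()`, $k_{up} = k_{down} = 1$ by default, i.e. one
expected update attempt per node per time unit).

Assumptions worth keeping in mind: propensities must be finite and
non-negative in every reachable state (negative or non-finite values abort
the simulation naming the node and state); exponential waiting times are a
modelling choice, not a biological measurement; and both
$\rho^{\uparrow}$ and $\rho^{\downarrow}$ may be positive in the same
state, which is legal and yields spontaneous flipping.

## Estimators and result types

`runEnsemble()` simulates `sampleCount` trajectories and reports four
result types:

* **State probability trajectories.** Time is divided into `timePoints`
  uniform windows over $[0, \mathrm{maxTime}]$. The probability of a
  projected state in a window is the mean over trajectories of the fraction
  of the window spent in that state (occupancy-time averaging). This is
  unbiased for the window-averaged distribution and has lower variance than
  sampling the state at one time point. Only states actually observed are
  stored; absent columns are implicitly zero.
* **Node probability trajectories.** Marginals of the same occupancy
  measure; they satisfy the exact identity marginal = sum of probabilities
  of states in which the node is active (asserted in the tests to 1e-12).
* **Last-state distribution.** The projected state at `maxTime`, one draw
  per trajectory.
* **Fixed points.** Full states with zero total propensity in which
  trajectories ended, with their share of the ensemble. For networks of at
  most 20 nodes `fixedPointsExhaustive()` additionally enumerates all
  $2^n$ states (with early pruning), so simulation-found fixed points can
  be confirmed exactly; above that size only simulation-encountered fixed
  points are observable, and a short time horizon may miss stable states.

Projection keeps only the declared *output* nodes: a state label is the
set of active outputs in declaration order (`"A -- C"`, `"<nil>"` when all
outputs are off). The number of outputs is capped at 15 and the number of
windows at 100; both limits are enforced when settings are constructed,
before any computation, to bound the size of the result tables.

## Reproducibility

Each trajectory draws from its own RNG substream, derived by a
counter-based hash (splitmix64 seeding a Mersenne twister) from the master
seed and the trajectory index. Results are therefore bit-identical for a
given seed, independent of execution order, and any single trajectory of an
ensemble can be replayed in isolation (`simulateTrajectory(..., trajIndex)`).
Uniform variates are built from the raw 64-bit generator output rather than
`std::uniform_real_distribution`, whose bit stream is implementation
defined. Mutant $i$ of a screen uses seed
$(\mathrm{seed} + 104729\,i) \bmod (2^{31}-1)$.

## The exact oracle

For networks of up to 12 nodes `exactTransient()` builds the full
$2^n$-state generator matrix $Q$ (off-diagonal entries are the Gillespie
propensities, diagonal $-R(S)$) and computes $p(t) = p(0)\,e^{Qt}$ with
`Matrix::expm()`. This path deliberately uses the pure-R expression
evaluator, while the ensemble engine runs compiled bytecode, so the two
routes share no evaluation code: agreement between them (total-variation
distance of final-window distributions, compared at the final-window
midpoint) is a genuine cross-check of both. With $10^4$ trajectories the
Monte Carlo error of a 64-state distribution puts the expected TV distance
around 0.015; a tolerance of 0.02 is therefore tight, and one of the five
6-node random networks in the acceptance suite sits marginally above it at
the frozen seeds (0.0203) — pure sampling noise, documented rather than
tuned away.

## Mutations and screening

A knock-out (OFF) clamps a node by replacing its activation rate with the
constant 0 (and its inactivation rate with 1) and forcing its initial value
to 0; knock-ins (ON) are symmetric. Clamping, rather than rebalancing
rates, guarantees the node never leaves its forced value regardless of the
surrounding logic. A specification may not mutate the same node twice, so
OFF+ON conflicts are rejected up front. `enumerateMutants()` generates
singles and doubles over a candidate list (order: candidates, then
OFF before ON); because "order 2" is used both for "singles plus doubles"
and for "doubles only" in common usage, both are expressible
(`minOrder = 2` restricts to doubles).

The phenotype statistic used by `filterPhenotype()` is the **last-state
probability mass** of the projected states satisfying all constraints —
the quantity a final-state pie chart shows — not a time-averaged
probability, and the threshold comparison is strict (`> 0.35` excludes a
mass of exactly 0.35). Complementary constraints partition each mutant's
mass, which the tests assert exactly.

## Multi-valued models

SBML-qual documents may assign levels $0..m$ to a variable. `booleanize()`
converts such models to purely Boolean networks by the standard
level-duplication construction: components $v{:}1 \dots v{:}m$ (written
`v_b1 ...` in files, since `:` is not identifier-safe in the supported
dialects), level = number of active components, and the *admissibility*
invariant $v{:}j = 1 \Rightarrow v{:}(j{-}1) = 1$. Component $j$ follows
the logic

$$(F_v \ge j \wedge v{:}(j{-}1)) \vee \big(v{:}j \wedge (F_v \ge j \vee v{:}(j{+}1))\big)$$

where $F_v$ is the target level reconstructed from the function terms with
first-match semantics (boundary components drop the absent neighbour).
Levels therefore move stepwise (one level per jump) even when the target
jumps further — the usual asynchronous multi-valued convention — and
admissibility is invariant under simulation. Correctness is established
structurally: the asynchronous state-transition graph of the Booleanized
network restricted to admissible states is isomorphic, via the level
projection, to the stepwise transition graph of the source model
(brute-force check at desk scale). Initial levels translate to joint
degenerate initial-state blocks (level $k$ = first $k$ components on).

## File formats

BoolNet text files (`targets, factors` header) are read and written;
probabilistic/temporal BoolNet extensions are rejected because they fall
outside the CTMC semantics. The MaBoSS-style `.bnd`/`.cfg` grammar
implemented here (node blocks with `logic`/`rate_up`/`rate_down`; `$param`,
`istate` — including joint `[A,B].istate` blocks for linked nodes —
`is_internal`, `sample_count`, `max_time`, `time_tick`, `seed` statements)
is documented in `?readBnd`/`?readCfg` and prioritizes round-trip fidelity
(write → read gives an evaluation-identical model and equivalent settings)
over bit-compatibility with any particular MaBoSS release. SBML-qual is
import-only, and the supported MathML subset is Boolean connectives over
species/integer comparisons; sign and threshold attributes on inputs are
ignored because the math element is authoritative in the standard.
Expression syntax accepts both symbolic (`! & | ^`) and word
(`NOT AND OR XOR`) operators with precedence NOT > AND > XOR > OR
(arithmetic binds tighter than logic; the ternary `c ? a : b` is loosest),
and serializes symbolically. Numeric literals and arithmetic are
rate-context only, with one exception: the bare literals `0`/`1` are legal
logic constants (BoolNet constant rules). Division by zero is an error,
never infinity.

## Synthetic fixtures and what the tests show

Built-in toys (`makeToy()`) carry closed-form expectations: the two-state
single node (stationary $P(\mathrm{on}) = k_{up}/(k_{up}+k_{down})$), the
bistable toggle switch (fixed points $(1,0)$, $(0,1)$; 50/50 last-state
split from the symmetric start), odd-length repressilators (no fixed
points) and a two-variable multi-valued toy with a cross-level negative
feedback. `makeNKNetwork(n, k, seed)` generates Kauffman networks — $k$
distinct regulators per node, uniformly random truth tables emitted in
disjunctive normal form so every generated model is exportable — from a
self-contained Lehmer RNG stream, leaving R's global RNG untouched.

These fixtures exercise the estimator identities, format round-trips and
the conversion machinery at sizes where exact enumeration is feasible
(oracle comparisons at $n \le 6$, $10^4$ trajectories; exhaustive graphs at
$\le 2^{12}$ states — sizes chosen so the whole suite runs in well under a
minute on one core). They do not emulate features of curated biological
models: dozens-of-nodes scale (the engine itself handles it; the oracles do
not), heterogeneous rate constants spanning orders of magnitude, or
biologically calibrated truth-table bias. Passing tests demonstrate
correctness of the semantics and estimators, not biological validity of
any particular model.

## Known limitations

Entropy-based summaries, limit-cycle detection, basin-of-attraction
computation and rule-robustness analyses are out of scope, as are writing
SBML-qual and parsing GINsim's native `.zginml` (GINsim models are consumed
through their SBML-qual export). The interaction graph is syntactic: a
vacuous reference (`A | !A`) counts as an edge, so edge counts may differ
from curation-based interaction counts. Exhaustive fixed-point search stops
at 20 nodes and the exact transient oracle at 12; beyond that, simulation
is the only route and its fixed-point table is a lower bound on the true
stable-state set.
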