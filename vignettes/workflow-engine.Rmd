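---
title: "Design of the flowmd work-graph engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design of the flowmd work-graph engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowmd)
```

## The model

`flowmd` separates the *specification* of simulation work from its
*execution*. A work graph is a directed acyclic graph whose nodes are
operations — units of computation with declared, kinded input and output
ports — and whose edges are data dependencies. Operation constructors
(`make_constant`, `join_arrays`, `read_input`, `mdrun`,
`commandline_operation`, factory-made operations, ...) add nodes and
return handles; outputs are exposed as **Futures**, proxies for values
that do not exist yet. Nothing runs at build time.

Calling `result()` on a Future resolves it: the executor computes the
ancestor set of the Future's node, walks it in topological order, and
executes exactly those nodes, caching every output per (node, ensemble
member). Three behavioural guarantees follow and are tested as
properties:

* **minimality** — nodes outside the ancestor set stay pending;
* **exactly-once** — a (node, member) executes at most once per session,
  so repeated `result()` calls, diamond topologies and forked chains
  reuse cached results;
* **determinism** — node ids are `opname-k` with a per-operation
  counter, topological ties break by insertion order, and per-(node,
  member) seeds derive from the session seed, so repeated runs produce
  identical graphs, logs and stochastic streams.

### Ensembles

The ensemble dimension is the only implicit parallel axis. Binding an
array where a scalar is expected fans a node out to width *n*; widths
combine by broadcasting — `Broadcast(n, 1) = n`, `Broadcast(n, n) = n`,
and any other pair of distinct widths > 1 is an error. We deliberately
allow only the 1 → n implicit broadcast: reshaping between unequal
ensemble widths has no single sensible meaning, and failing fast on it
catches wiring mistakes. `gather()` is the explicit inverse: it delivers
all members of a source as one array, ordered by 0-based member index.
(Member-index order is a convention we fixed because *some* order must
be stated; nothing upstream prescribes one.)

### Kinds

The port type system is nominal and minimal: `boolean`, `integer`,
`real`, `text`, `file_path`, `array_of(...)` to depth 2, and two
pragmatic extensions — an opaque `data` kind for structured payloads
(run inputs, systems, data frames) and `any` for ports whose kinds are
inferred from bound values (wrapped user procedures, the empty array's
element kind). There is no implicit coercion, not even integer → real:
a mismatch is almost always a wiring bug, and the cost of an explicit
`as.numeric` is trivial next to the cost of a silently mistyped
simulation parameter.

## Execution strategy

Uncoupled operations (everything but simulation-category ensemble
nodes) execute sequentially in DAG order. Ensemble `mdrun` nodes are
**co-executed**: all members advance through one interleaved
(round-robin) step loop. That realizes two contracts that sequential
member execution cannot:

* **ensemble reduction is a barrier** — every `mean_distance` reduce
  epoch completes only when all members have contributed their value
  for that epoch, and all members observe the *identical* reduced value;
* **ensemble-scope stop** — a stop signalled by any member halts every
  member at its next step boundary (stop latency ≤ 1 step).

Reduce epochs are implicit call-count matching: epoch *k* is the *k*-th
reduce of each member. A member whose plugin configuration reduces while
another's does not — or a member that leaves a reducing ensemble early
via a member-scope stop — makes epochs unmatchable and raises
`reduce-epoch-mismatch`; we chose the error over padded or ragged
reductions because a silently shrinking mean changes the statistic being
computed. Failure policy is fail-fast: the first member failure aborts
the ensemble with the node and member named in the error.

Co-execution here is an interleaving contract, not a performance
feature; there is no thread, process or MPI parallelism.

## Control flow

`subgraph()` declares named state variables (kind + initial value) and a
body that may instantiate any operation, reading the variables as
Futures and returning updates. `while_loop()` repeats the body while a
condition holds, up to a mandatory `max_iteration` guard — required
because with deferred execution a runaway loop is otherwise undetectable
at build time; exhausting the guard is not an error, and
`iterations_run` reports the count.

Two semantic choices were genuinely open and are fixed as follows:

* **Pre-test** (`while`), not post-test (`do-while`): the condition is
  evaluated on the current state *before* each iteration, so a condition
  false on the initial state yields zero iterations. This matches the
  construct's name; the alternative was defensible but one had to be
  chosen and documented.
* The condition sees **end-of-iteration state** only, never values
  computed mid-body.

Graph growth is literal: each iteration injects the current state as
fresh constant nodes and instantiates a fresh copy of the body, all
visible in the execution log. The equivalence oracle — a while loop must
produce bit-identical final state to an explicitly scripted loop calling
the body the same number of times — is tested with a simulation body
under fixed seeds. Conditions over ensemble-width variables must pass
through explicit `ensemble_any()`/`ensemble_all()` reductions; a
boolean of width > 1 is ambiguous as a loop gate and is rejected.

Wrapped operations may not add graph nodes during execution; only the
loop construct extends the graph dynamically. This keeps the executed
log interpretable as "the loop grew the graph" rather than "anything
may have".

## The toy MD engine

The engine exists to exercise the workflow and plugin contracts, not to
do chemistry: point particles with harmonic bonds, no nonbonded terms,
neighbour lists, periodic boundaries or constraints. All quantities are
in reduced units (masses, lengths, times dimensionless) — the API makes
no physical-unit claims, and a unit system would add surface without
covering more behaviour.

* **Integrator**: velocity Verlet. Positions advance by
  `v dt + f/(2m) dt²`; velocities by the mean of old and new forces
  times `dt/(2m)`. For the dimer test system this is symplectic and
  second-order: relative energy drift at `dt = 0.001` over 10⁴ steps is
  ≈ 5 × 10⁻⁷, and halving `dt` reduces it ≈ 4×.
* **Friction** is a deterministic damping force `−γ m v` (evaluated with
  the pre-step velocity on both force evaluations of a step), *not* a
  Langevin thermostat — no random kicks. This keeps the relaxed state of
  a bonded + restrained pair exactly at the minimum of the summed
  quadratic potentials, `(k_b r_0 + k_r t)/(k_b + k_r)`, which the tests
  check in closed form. A stochastic thermostat is a documented
  extension, not a hidden feature.
* **Plugins** follow an in-process callback contract: per step, the
  restraint sees the restrained pair's positions (restrained-site view
  only — the restraint use case needs nothing more), contributes a force
  of magnitude `k_r (d − target)`, may signal a stop when
  `|d − target| < stop_tolerance` with member or ensemble scope, and may
  contribute `d` to the ensemble mean each output interval. Mean (not
  sum) reduction was chosen because it is scale-free in member count,
  which is what a restrained-ensemble update consumes. Any plugin field
  may be a length-*n* vector, giving per-member configuration (e.g.
  per-member targets). An empty plugin list shares the code path of a
  plugin-free run and produces bit-identical trajectories.
* **Seeds**: `params.seed = 0` keeps the input velocities unchanged
  (exact, reproducible fixtures); `seed > 0` draws small Gaussian
  initial velocities (sd 0.05), the mechanism by which an ensemble
  fanned out over seeds produces distinct member trajectories.
* **Outputs**: XYZ trajectory frames plus a JSON-lines energy side
  file, written under `<workdir>/<node_id>/<member>/`; per-task
  directories are never reused, which is what makes fork-without-
  re-execution safe on the filesystem. Input files are referenced in
  place, not copied — tools that write next to their inputs are
  unsupported and documented as such.

Degenerate inputs are errors with classed conditions: non-finite
coordinates raise `numeric-overflow` (time step too large), coincident
bonded or restrained particles raise `degenerate-geometry` (the force
direction is undefined), and invariant violations name the offending
field (`system.masses[2]`).

## The synthetic generators

`generate_random_dag()` emits graphs of no-op operations with edges only
from lower to higher construction index — acyclic by construction, then
independently re-checked — as the test surface for executor properties.
`make_dimer()` builds the canonical two-particle fixture (defaults:
`dt = 0.001`, 10⁴ steps, γ = 0, a frame every 10 steps). The target
distributions of the restrained-ensemble demo are Gaussian mixtures; the
default is bimodal (centers 3 and 5, sd 0.3, equal weights), a typical
shape for spin-label pair-distance measurements at the scale of reduced
units used here.

What these generators deliberately do not emulate: real force fields,
solvent, measurement noise in the target distributions, and
cluster-scale ensemble counts. Passing tests therefore demonstrate that
the *orchestration semantics* (dependency resolution, ensemble
accounting, plugin/stop/reduce contracts, loop state propagation) and
the *integrator's numerics* are correct — not that any chemical
observable is realistic.

## Problem sizes and tolerances

The shipped tests and the acceptance script use: 200 random DAGs of ≤ 12
nodes for the minimal-execution oracle; 10⁴–2×10⁴ integrator steps for
conservation and period checks (tolerances 10⁻⁶ relative drift and 1%
on the period, both comfortably above the integrator's measured error at
these step sizes); 6×10³ damped steps for the restraint equilibrium (2%
tolerance on an exact closed form); and 64 members for the restrained
ensemble, judged against the 5% asymptotic KS critical value
`1.3581/√n`. These sizes were chosen so every property is measured well
inside its asymptotic regime while the whole suite stays interactive on
a single CPU.

## Known limitations

* Serialization records closures (wrapped procedures, subgraph bodies,
  loop conditions) by registry name only; deserialization requires
  re-registration. Two different wrapped operations sharing a registry
  name will collide on rebuild.
* `stdin` may be a Future for symmetry with file inputs, an extension
  beyond the minimal wrapping contract.
* Ensemble fan-out of command inputs accepts lists of constant paths or
  a single file Future; lists mixing Futures per member are not
  supported.
* The engine is single-process; co-execution is cooperative
  interleaving, and wall-clock scaling with member count is linear.
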