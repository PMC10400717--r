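---
title: "Growing neurons as interacting agents: the neurogrow model and engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growing neurons as interacting agents: the neurogrow model and engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurogrow)
```

## The model

neurogrow simulates neural development as a population of *fronts*:
autonomous growth agents that are either spheres (somata) or capsules
(cylinders with a radius, representing neurite segments). Time advances in
discrete *cycles*; the cycle is an abstract unit that may stand for
anywhere from one to a hundred hours of developmental time, so no physical
time conversion is offered. Each cycle, every enabled front executes the
growth rule of its neuron type exactly once. A rule typically does one of
four things:

* **extend** — create one child capsule at its distal tip;
* **branch** — create two (or more) children, usually with a tapered radius;
* **migrate** — somata only, before any dendrite exists: move toward the tip
  of a single leading filipodium, optionally laying down a trailing axon;
* **terminate or retract** — disable itself, or schedule the pruning of a
  terminal front or a whole branch.

The defining constraint is *strict collision avoidance*: no new structure
may overlap an existing one. Two fronts overlap when the minimum distance
between their axis segments is smaller than the sum of their radii; touching
(distance exactly equal to the radius sum) is not an overlap. A sphere is a
degenerate capsule (a zero-length segment plus a radius), which lets one
distance primitive serve all shape pairs.

A front's geometry is given by a proximal coordinate `orig` and a distal
coordinate `end`. Only `end` is chosen by the growth rule: children of
cylinders start at their parent's `end`, and children of somata start on the
soma surface along the ray from the centre to the requested position. Thus a
position 15 um from the centre of a 10 um soma yields a 5 um root — and the
accumulated `path_length`, measured from a front's `end` back to the soma
centre, of that root is 15 um. Growth rules normally branch on
`path_length`, as the bundled example model does when it stops growing at
100 um.

### Structural contacts are not collisions

Three kinds of contact are built into the tree geometry and are therefore
excluded from collision tests and from the package's no-overlap invariant:

1. a child against its parent (they share an anchor point);
2. branch siblings that share their origin point (their axis distance is
   zero by construction; without this exclusion branching would be
   geometrically impossible);
3. a migrating soma against its own trailing-axon chain, which is deposited
   in the space the soma has just vacated and hugs it on curved paths.

Dendritic roots of the same soma have distinct surface origins and *are*
tested against each other, as are all unrelated fronts.

## Collision detection and the grid

Testing a proposed front against every existing front is quadratic and
dominates run time, so the volume is covered by a cubic lattice with spacing
`grid_step` (default 20 um). Every front is registered at one or more
lattice points (*gids*); a query tests only fronts registered at the
candidate's gids and their 26 neighbours.

The allocation rule samples the capsule axis at intervals of at most half a
grid step (endpoints included); each sample is assigned to its nearest
lattice point plus any lattice point at most a quarter grid step further
away than the nearest. This guarantees at least one gid per front and — for
fronts with radius at most half the grid step — that any two overlapping
fronts occupy gid sets within one lattice step of each other, making the
restricted query exactly equivalent to brute force. The suite verifies that
equivalence on random scenes at `grid_step` 5, 10 and 20 um, and the engine
warns once if a front's radius exceeds half the grid step, where the
guarantee no longer holds; the remedy is a larger `grid_step`.

Registered ids are stored in linked blocks (default 10 slots) inside a
fixed-size array partitioned into per-core sections; a full block chains to
a continuation block, moving its last resident entry into the new block.
Deregistration replaces the removed entry with the chain's last entry, and a
gid whose chain empties is reset to zero with its blocks recycled.
`grid_stats()` reports the occupancy metrics that matter when tuning
`grid_step` against the model's typical front length: mean gids per front,
grid occupancy, the fraction of occupied points holding 1–5 and 1–10
fronts, and the maximum per-point load.

## The engine and its failure vocabulary

All failures a rule is expected to handle are classed conditions:
`collisionError` (carrying the first colliding front), `insideParentError`,
`volumeError`, `gridCompetitionError`, `overflowError` (naming the
exhausted array), `notSelfError`, plus `usageError` for contract
violations. The canonical rule shape is trial and error: catch the error,
try the next random point. `add_child()` is atomic — a failed attempt
leaves no trace in the store, the grid, or the lock tables — because retry
loops assume failed attempts are free.

Retractions are deliberately not applied when requested. They queue during
the cycle and the admin applies them serially at the cycle's end: flags set,
grid entries removed, child lists unlinked, attached synapses expired.
Retracted fronts are never physically deleted; they keep their store slot
and database row with a `death_cycle`, which preserves full history and
keeps the fixed-size arrays simple. Single-front retraction is restricted to
terminal fronts; whole subtrees go through `retract_branch()`.

## The shared-memory design, realised deterministically

The engine implements a shared-memory parallel architecture: all state lives
in fixed-capacity arrays partitioned into `num_workers + 1` equal private
sections (section 1 belongs to the admin, which creates only somata); a core
writes fronts only into its own section, so allocation is conflict-free and
a front id — a (subclass row, index) pair with index 0 meaning *empty* —
encodes its creator. The admin drives each cycle: it fills each worker's
two-slot instruction mailbox (two ids while the backlog is large, one near
exhaustion, then an end-of-cycle sentinel), schedules growing fronts first,
then migrating, then other active ones, and defers any front whose grid
points are already write-locked, after first taking preliminary write locks
on the gids of everything it schedules. Workers clear an instruction slot
before processing it (the "started" signal), run the rule, and append
(id, symbol) records to their results mailbox, which the admin consumes for
storage.

Grid access is arbitrated by a two-stage lock broker over per-gid read and
write lock tables, with one request cell per core. A *preliminary* write
lock announces intent and still admits readers; the *full* lock, requested
as a negated gid by the preliminary holder, excludes everything while the
actual write happens (the broker also refuses the upgrade until pending
reads have drained, since a full lock and a live reader would race). Only
the broker writes grants; holders release by zeroing their entry. A request
not granted within the timeout raises `gridCompetitionError`; per-cycle
counts per worker are kept and summarised by `competition_stats()`.

R offers no shared-memory threads, so the concurrency is realised as a
deterministic cooperative step machine inside one process: simulated
workers interleave at front granularity, the broker runs between steps on
the admin's thread of control, and the lock timeout counts broker steps — a
logical clock in place of the 1 s wall-clock budget — so timeout behaviour
is reproducible in tests. Every protocol-level property is real and
audited: mutual exclusion on the lock tables, exactly-once dispatch,
private-section discipline, and balanced grant/release ledgers, all checked
by instrumented stress tests and by step-for-step replays of the worked
read-lock, write-lock and private-allocation sequences. What is *not*
reproduced is OS preemption; the package therefore makes the same promise a
true shared-memory implementation makes, but for the opposite reason:
multi-worker runs use per-worker RNG streams and interleaved scheduling, so
they are statistically equivalent to serial runs without being individually
reproducible, while `num_workers = 1` (serial mode) is bit-reproducible —
identical seeds give byte-identical trace databases and SWC files.

Worker RNG streams are re-seeded from a hash of (seed, core, cycle) at
every cycle boundary. Besides keeping serial runs reproducible, this makes
resume exact: importing a trace database and continuing in serial mode
reproduces the remainder of an uninterrupted run front for front.

## Environment: substrate and synapses

Substrate sources are point releases with an amount `n_mol` and a diffusion
constant `D`. The concentration at distance `r`, `t` cycles after release,
is the instantaneous point-source solution
`C(r, t) = n_mol (4 pi D t)^{-3/2} exp(-r^2 / (4 D t))`, summed over
sources, with `t = 0` treated as one cycle of spreading. Stochastic
sensing — the default, emulating a growth cone counting molecules — draws
Poisson(`C x v`) with a probe volume `v` of 1 um^3; the suite checks the
mean and the Poisson mean-variance signature. Fronts may also secrete
substrate at their tip each cycle, which builds up the steady-state field of
a continuous source (`n_mol / (4 pi D r)` per source); the migration demo
uses this because a single instantaneous release cannot be both detectable
at 100 um early and steeply graded near the source late.

Synapses connect a pre- and a postsynaptic front whose surface-to-surface
separation is at most `max_distance` (default 0.5 um — the model only
requires "nearby", so this is a package constant with an argument to
override). They occupy no space, are removed automatically when either
endpoint retracts, and carry a weight updated by the rate-product Hebbian
rule `w' = w + eta r_pre r_post`. The pruning demo wires prescribed synapse
counts onto eight dendrites and retracts, in one cycle, every branch with
fewer than five — reproducing the classic instantaneous-pruning experiment.

## Storage

The trace is an event-sourced SQLite database written in one transaction
per cycle: front creations insert rows, retractions set `death_cycle`,
migrations append to a history table, plus synapse, substrate, neuron and
metadata tables under a schema version tag. The schema is this package's
own design; it records what the engine produces (fronts with geometry and
tree links, migration positions, retractions, synapses, substrate, optional
per-front attributes) and is sufficient to reconstruct the state at any
committed cycle. `export_swc()` writes standard 7-column SWC per neuron:
sample 1 is the soma (type 1), each live cylinder contributes its distal
coordinate with a parent link in depth-first creation order; retracted
fronts are absent.

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `grid_step` | 20 | um | collision-grid spacing; match to typical front length |
| `block_size` | 10 | ids | linked-block capacity per grid point |
| `section_size` | 2000 | fronts | private store section per core and type |
| `lock_timeout` | 25 | broker steps | logical stand-in for the 1 s lock budget |
| `num_workers` | 1 | cores | 1 = reproducible serial mode |
| taper factor | 0.9 | — | branch-child radius multiplier |
| synapse `max_distance` | 0.5 | um | proximity threshold for synapse creation |

The example model's constants (five roots from ten candidates, 15 um root
displacement, 94 %/6 % extension/branching, 20 degree cone, 5 um steps,
100 um termination, 10 um soma) are the printed parameters of the canonical
random-growth script and are the package's reference fixture.

## Numerical and design choices

* **Segment distance** uses the classic clamped closest-point
  parameterisation with explicit handling of degenerate (zero-length)
  segments; tests compare it against an independent golden-section convex
  search at 10^-3 um tolerance.
* **Cone sampling** is uniform in solid angle on the spherical cap (the
  alternative, uniform in angle, over-weights the cone axis); a zero
  aperture returns the heading exactly.
* **Branch direction sampling** is uniform on the sphere with whole-set
  rejection until all pairwise separations reach `180/n` degrees, which
  keeps candidate roots well spread without biasing any direction.
* **Taper** is a single multiplicative factor — the minimal faithful
  contract for a "smaller radius relative to the parent".
* **Dispatch order** within a scheduling category is ascending front id,
  which fixes the serial trajectory; first-hit collision scan order is
  ascending gid then block order for the same reason.
* **Path length of soma children** includes the soma radius (distance from
  the child's `end` to the soma *centre*). The alternative — measuring from
  the surface — breaks the printed root arithmetic (15, 20, 25, ... um
  along a straight root chain).
* **Extension retries** are capped (default 100) before a blocked tip gives
  up and disables itself; an uncapped loop livelocks in fully enclosed
  scenes.
* **Deadlock safety valve**: if every remaining front in a cycle sits on
  write-locked gids while all instruction slots are empty, deferral cannot
  make progress and the scheduler dispatches the backlog head anyway. This
  cannot trigger in a correct run; it bounds the damage of a protocol bug.

## The demos as study conditions, and their limits

The random-growth fixture runs one soma in a 200 um cube for 30 cycles
(about 60–250 fronts depending on branching luck); the acceptance script
runs it to completion across several seeds. The migration demo starts a
soma 100 um from a line of five secreting sources (`n_mol` 4x10^7 per
cycle, `D` 200 um^2/cycle, stop threshold 2000 molecules, 5 um steps, 10 um
filipodium) and reliably approaches to ~25 um before the high-concentration
stop triggers; these values were chosen once so that the sensed Poisson
counts give a usable gradient at the start distance, and are fixture
parameters, not library constants. Scale-wise the test suite stays at a few
hundred fronts per run — ample for every structural and statistical
property checked, but three orders of magnitude below the hundreds of
thousands of fronts the architecture is designed to hold, so the suite says
nothing about wall-clock scaling. The synthetic demos also idealise real
data: growth rules see a noiseless tree, substrate diffusion ignores
boundaries and degradation, and neuron counts are small.

## Known limitations

* No progenitor proliferation or tissue expansion; the volume is fixed, so
  long simulations crowd artificially.
* No post-hoc diameter growth; radii are fixed at creation.
* Migration requires a dendrite-free soma (one filipodium plus a trailing
  axon chain at most).
* Multi-worker runs are simulated concurrency: statistically faithful,
  including grid-competition behaviour, but not a measurement of parallel
  speed-up.
* Front user attributes are fixed per subclass at definition time; there
  are no per-instance dynamic fields.
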