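# neurogrow

Agent-based simulation of neural development in R. Neurons are grown — not
wired — by populations of *fronts*: autonomous sphere (soma) and capsule
(neurite segment) agents that extend, branch, migrate and retract over
discrete cycles under user-written growth rules, with strict collision
avoidance between all structures. The package is aimed at computational
neuroscientists who want to study how physical interaction, chemical cues
and activity-dependent pruning shape dendritic and axonal morphologies
while many cells develop simultaneously in one volume.

## The model in brief

A front is a capsule with proximal coordinate `orig`, distal coordinate
`end` and a radius; a soma is a sphere (a degenerate capsule). Two fronts
collide when the minimum distance between their axis segments, `d(S1, S2)`,
satisfies

    d(S1, S2) < r1 + r2        (touching is not a collision)

and no new front may collide with an existing one. Collision detection is
accelerated by a uniform lattice with spacing `grid_step`: each front is
registered at its nearby lattice points, and a query tests only fronts
registered at the candidate's points and their 26 neighbours, which is
provably equivalent to the all-pairs test for fronts thinner than half the
grid spacing.

Each cycle, every enabled front runs its type's growth rule once
(`manage_front` style, with the front as `self`), creating children with
`add_child()`, migrating with `migrate_soma()` (somata led by a filipodium,
optionally trailing an axon), or scheduling pruning with `retract()` /
`retract_branch()`; retractions apply serially at the cycle's end. Failures
arrive as catchable classed conditions (`collisionError`, `volumeError`,
`gridCompetitionError`, ...), so rules grow by trial and error. Diffusible
substrate with stochastic (Poisson) sensing and proximity-based synapses
with Hebbian weight updates provide environmental and activity signals.

State lives in fixed-size arrays partitioned into per-core private
sections, scheduled through two-slot instruction mailboxes and guarded by a
two-stage (preliminary/full) grid lock broker — a shared-memory parallel
design realised here as a deterministic cooperative step machine. One
worker is reproducible serial mode: identical seeds give byte-identical
SQLite trace databases and SWC exports. Multi-worker runs interleave
per-worker RNG streams and are statistically equivalent without being
individually reproducible.

## A worked example

The bundled random-growth model: one 10 um soma grows five dendritic roots
from ten candidate directions (each root's distal end 15 um from the soma
centre), then every tip either extends (94 %, one 5 um front within a
20-degree cone) or branches (6 %, two tapered children) until its path
length back to the soma reaches 100 um.

```r
library(neurogrow)
sim <- run_random_growth(seed = 42, n_cycles = 30)
print(sim)
#> <neural development simulation>
#>   cycle: 30
#>   volume: [-100, -100, -100] - [100, 100, 100] um
#>   types: random_growth
#>   workers: 1
#>   fronts: 143 live / 143 created

st <- sim$store
sum(st$used & st$shape == 2 & st$num_children == 2)  # branch points
#> [1] 7
max(st$path_length[st$used])                          # termination bound
#> [1] 100

grid_stats(sim)
#>   mean_gids_per_front  occupancy  frac_1_5 frac_1_10 max_fronts_per_gid
#> 1            3.230769 0.05184072 0.4492754 0.8115942                 22

export_swc(sim, "rand_neuron_1", "example.swc")
```

The run produced 143 fronts: the soma, its five roots, and their
extensions/branches, none overlapping any other (the suite sweeps this
invariant after every cycle). `grid_stats()` says each front occupies ~3.2
grid points at the default 20 um spacing and the busiest grid point indexes
22 fronts — the numbers to watch when tuning `grid_step`. The SWC file
reloads in any morphology tool; sample 1 is the soma, every other sample is
a front's distal coordinate with its parent link.

Other entry points: `migration_demo()` (filipodium-led chemotaxis toward
secreting sources, with obstacle avoidance and a trailing axon),
`retraction_demo()` (synapse-count-dependent branch pruning in one cycle),
and a shell interface:

```sh
Rscript inst/cli/neurogrow.R run random --seed 1 --cycles 20 --db trace.db
Rscript inst/cli/neurogrow.R export-swc --db trace.db --neuron rand_neuron_1 --out n1.swc
Rscript inst/cli/neurogrow.R stats --db trace.db
Rscript inst/cli/neurogrow.R resume --db trace.db --cycles 10
```

See `vignettes/neurogrow-methods.Rmd` for the full account of the model,
the grid and locking design, and every tunable parameter.

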