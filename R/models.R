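# Example models -----------------------------------------------------------------

#' Parameters of the random-growth example model
#'
#' The canonical small model: a soma grows five dendritic roots, which then
#' extend stochastically (94% probability, one 5 um front within a 20-degree
#' cone of the current heading) or branch (6% probability, two tapered
#' children), terminating once the accumulated path length from the distal
#' coordinate back to the soma reaches 100 um.
#'
#' @param soma_radius soma radius (um).
#' @param n_roots dendritic roots to grow from the soma.
#' @param n_candidates candidate directions sampled around the soma.
#' @param root_length length of the displacement vector from the soma centre
#'   used to place each root's distal coordinate (um).
#' @param root_radius radius of dendrite roots (um); dendrites are thinner
#'   than the soma.
#' @param extension_prob probability of an extension event; branching has
#'   probability `1 - extension_prob`.
#' @param cone_angle extension cone half-angle (degrees).
#' @param step_length extension front length (um).
#' @param max_path_length growth terminates at or beyond this path length (um).
#' @param taper_factor branch children radius factor.
#' @param branch_candidates candidate directions per branching event (two
#'   children are kept).
#' @param extension_retry retry budget for a blocked extension before the
#'   tip gives up and is disabled.
#' @return a named list of parameters.
#' @export
random_growth_params <- function(soma_radius = 10, n_roots = 5L,
                                 n_candidates = 10L, root_length = 15,
                                 root_radius = 2, extension_prob = 0.94,
                                 cone_angle = 20, step_length = 5,
                                 max_path_length = 100, taper_factor = 0.9,
                                 branch_candidates = 4L,
                                 extension_retry = 100L) {
  as.list(environment())
}

#' The random-growth example neuron type
#'
#' Builds the [neuron_type()] implementing the random-growth rule described
#' in [random_growth_params()]. The rule is the standard trial-and-error
#' growth pattern: every failed attempt (collision, volume border, grid
#' competition) simply tries the next random point.
#'
#' @param params a [random_growth_params()] list.
#' @return an `ng_neuron_type`.
#' @export
random_growth_type <- function(params = random_growth_params()) {
  p <- params
  grow <- function(sim, self) {
    st <- sim$store
    if (st$order[self] == 0L) {
      # soma: grow roots by trial and error until n_roots succeed or the
      # candidate points run out, then never grow again
      pts <- unit_branching_sample(p$n_candidates)
      num_dend <- 0L
      for (i in seq_len(nrow(pts))) {
        new_pos <- st$orig[self, ] + pts[i, ] * p$root_length
        made <- tryCatch(add_child(sim, self, new_pos, radius = p$root_radius),
                         ng_error = function(e) 0L)
        if (made != 0L) num_dend <- num_dend + 1L
        if (num_dend >= p$n_roots) break
      }
      disable_front(sim, self)
    } else if (st$path_length[self] < p$max_path_length) {
      if (stats::runif(1L) < p$extension_prob) {
        # extension: one front within the cone, redrawing on failure
        heading <- st$end[self, ] - st$orig[self, ]
        heading <- heading / norm3(heading)
        for (i in seq_len(p$extension_retry)) {
          dir <- unit_heading_sample(heading, p$cone_angle)
          new_pos <- st$end[self, ] + dir * p$step_length
          made <- tryCatch(add_child(sim, self, new_pos),
                           ng_error = function(e) 0L)
          if (made != 0L) break
        }
        disable_front(sim, self)
      } else {
        # branching: like root creation but with fewer random points and a
        # tapered radius
        pts <- unit_branching_sample(p$branch_candidates)
        r <- taper(st$radius[self], p$taper_factor)
        made <- 0L
        for (i in seq_len(nrow(pts))) {
          new_pos <- st$end[self, ] + pts[i, ] * p$step_length
          ok <- tryCatch(add_child(sim, self, new_pos, radius = r),
                         ng_error = function(e) 0L)
          if (ok != 0L) made <- made + 1L
          if (made >= 2L) break
        }
        disable_front(sim, self)
      }
    } else {
      disable_front(sim, self)                 # growth termination
    }
  }
  neuron_type("random_growth", grow, params = p)
}

#' Run the random-growth example model
#'
#' Convenience wrapper: one soma in a cube, grown for `n_cycles` cycles.
#'
#' @param seed random seed.
#' @param n_cycles number of cycles.
#' @param num_workers simulated processing cores.
#' @param params model parameters.
#' @param volume_half half-width of the cubic volume (um).
#' @param db optional trace database path.
#' @param soma_pos soma centre; default the volume centre.
#' @return the simulation object.
#' @export
run_random_growth <- function(seed = 1L, n_cycles = 30L, num_workers = 1L,
                              params = random_growth_params(),
                              volume_half = 100, db = NULL,
                              soma_pos = c(0, 0, 0), grid_step = 20) {
  sim <- new_simulation(rep(-volume_half, 3L), rep(volume_half, 3L),
                        list(random_growth_type(params)), seed = seed,
                        num_workers = num_workers, db = db,
                        grid_step = grid_step)
  add_neurons(sim, "random_growth", "rand_neuron", n = 1L,
              soma_radius = params$soma_radius, placement = "explicit",
              positions = matrix(soma_pos, 1L, 3L))
  simulation_loop(sim, n_cycles)
  sim
}

# Migration demo -----------------------------------------------------------------

#' Soma migration demo: filipodium-led chemotaxis with a trailing axon
#'
#' A migrating soma explores with a single leading filipodium: each cycle it
#' either (re)grows the filipodium toward the strongest sampled substrate
#' concentration, or migrates one step toward the filipodium tip and sheds
#' it. When the sensed concentration at the filipodium tip exceeds
#' `stop_conc` the filipodium is retracted and migration stops. A trailing
#' axon is extended automatically behind the soma. Obstacle somata are inert
#' and simply repel the path through collision detection.
#'
#' @param seed random seed.
#' @param n_cycles cycles to run.
#' @param soma_pos starting soma centre.
#' @param source_pos matrix of substrate source positions (default: five
#'   sources along a line).
#' @param obstacles optional matrix of obstacle soma centres.
#' @param soma_radius,obstacle_radius radii (um).
#' @param n_mol molecules secreted per source per cycle. Sources secrete
#'   every cycle, so the field approaches the steady state of a continuous
#'   point source, `n_mol / (4 pi D r)` per source -- steep near the source
#'   and sensed far away once the front of the field arrives.
#' @param D diffusion constant (um^2/cycle).
#' @param soma_step migration step per cycle (um).
#' @param fil_length filipodium length (um).
#' @param stop_conc sensed concentration (molecule count) above which the
#'   filipodium retracts and migration stops.
#' @param trailing_axon grow a trailing axon?
#' @param num_workers simulated cores.
#' @param db optional trace database path.
#' @return the simulation object.
#' @export
migration_demo <- function(seed = 1L, n_cycles = 50L,
                           soma_pos = c(-60, 0, 0),
                           source_pos = cbind(seq(40, 80, 10), 0, 0),
                           obstacles = NULL,
                           soma_radius = 5, obstacle_radius = 5,
                           n_mol = 4e7, D = 200, soma_step = 5,
                           fil_length = 10, stop_conc = 2000,
                           trailing_axon = TRUE, num_workers = 1L, db = NULL) {
  grow <- function(sim, self) {
    st <- sim$store
    if (st$shape[self] != SHAPE_SPHERE) return(invisible(NULL))
    fil <- st$filipodium[self]
    if (fil == 0L) {
      # no filipodium: probe directions, grow one toward the best sensed
      # concentration; also lay down the axon root on the first call
      dirs <- unit_branching_sample(8L)
      conc <- apply(dirs, 1L, function(d) {
        sample_concentration(sim, st$orig[self, ] +
                               d * (st$radius[self] + fil_length), "cue")
      })
      best <- dirs[which.max(conc), ]
      if (trailing_axon && !st$has_trailing_axon[self]) {
        back <- st$orig[self, ] - best * (st$radius[self] + 2)
        tryCatch(add_child(sim, self, back, radius = 0.5, kind = "axon"),
                 ng_error = function(e) NULL)
      }
      tip <- st$orig[self, ] + best * (st$radius[self] + fil_length)
      tryCatch(add_child(sim, self, tip, radius = 0.4, kind = "filipodium"),
               ng_error = function(e) NULL)
    } else {
      conc_tip <- sample_concentration(sim, st$end[fil, ], "cue")
      if (conc_tip >= stop_conc) {
        # arrived: drop the filipodium and stop migrating
        retract_branch(sim, self, fil)
        disable_front(sim, self)
        return(invisible(NULL))
      }
      dir <- st$end[fil, ] - st$orig[self, ]
      dir <- dir / norm3(dir)
      new_pos <- st$orig[self, ] + dir * soma_step
      tryCatch(migrate_soma(sim, self, new_pos),
               ng_error = function(e) NULL)
      # shed the filipodium; a fresh one is grown next cycle
      retract_branch(sim, self, fil)
    }
    invisible(NULL)
  }
  inert <- function(sim, self) disable_front(sim, self)
  secrete <- function(sim, self) {
    secrete_substrate(sim, self, "cue", n_mol = n_mol, D = D)
  }
  sim <- new_simulation(c(-100, -100, -100), c(100, 100, 100),
                        list(neuron_type("migrator", grow),
                             neuron_type("obstacle", inert),
                             neuron_type("source", secrete)),
                        seed = seed, num_workers = num_workers, db = db)
  src <- add_neurons(sim, "source", "source", soma_radius = 0.5,
                     placement = "explicit", positions = source_pos)
  for (s in src) enable_front(sim, s, "active")
  deposit_substrate(sim, "cue", source_pos, n_mol = n_mol, D = D)
  soma <- add_neurons(sim, "migrator", "migrator", soma_radius = soma_radius,
                      placement = "explicit",
                      positions = matrix(soma_pos, 1L, 3L))
  enable_front(sim, soma, "migrating")
  if (!is.null(obstacles)) {
    obs <- add_neurons(sim, "obstacle", "obstacle", soma_radius = obstacle_radius,
                       placement = "explicit", positions = obstacles)
    for (o in obs) disable_front(sim, o)
  }
  simulation_loop(sim, n_cycles)
  sim
}

# Retraction demo ------------------------------------------------------------------

#' Synapse-dependent pruning demo
#'
#' Builds a neuron with radial dendrite chains, an axon-bearing neuron whose
#' fibres run alongside them making prescribed numbers of synapses, and then
#' runs one cycle in which every dendrite branch with fewer than
#' `min_synapses` synapses is retracted in its entirety.
#'
#' @param synapse_counts integer vector: number of synapses per dendrite
#'   (one dendrite chain per entry).
#' @param min_synapses pruning threshold: branches with fewer live synapses
#'   are retracted.
#' @param chain_len fronts per dendrite chain.
#' @param seed random seed.
#' @return a list with the simulation, the dendrite root ids, the per-branch
#'   synapse counts and the ids of retracted roots.
#' @export
retraction_demo <- function(synapse_counts = c(0L, 1L, 2L, 3L, 4L, 5L, 6L, 9L),
                            min_synapses = 5L, chain_len = 10L, seed = 1L) {
  n_dend <- length(synapse_counts)
  roots <- integer(n_dend)
  prune <- function(sim, self) {
    st <- sim$store
    for (ch in children_of(st, self)) {
      if (count_synapses(sim, ch, branch = TRUE) < min_synapses) {
        retract_branch(sim, self, ch)
      }
    }
    disable_front(sim, self)
  }
  inert <- function(sim, self) disable_front(sim, self)
  sim <- new_simulation(c(-150, -150, -150), c(150, 150, 150),
                        list(neuron_type("pruned", prune),
                             neuron_type("axons", inert)),
                        seed = seed)
  soma <- add_neurons(sim, "pruned", "red", soma_radius = 5,
                      placement = "explicit", positions = matrix(0, 1L, 3L))
  ax_soma <- add_neurons(sim, "axons", "ax", soma_radius = 5,
                         placement = "explicit",
                         positions = matrix(c(0, 0, 60), 1L, 3L))
  disable_front(sim, ax_soma)
  step <- 5
  dend_r <- 0.5; axon_r <- 0.2; z_off <- 1.0
  for (k in seq_len(n_dend)) {
    ang <- 2 * pi * (k - 1) / n_dend
    dir <- c(cos(ang), sin(ang), 0)
    # dendrite chain
    parent <- soma
    dend <- integer(chain_len)
    for (i in seq_len(chain_len)) {
      pos <- dir * (5 + i * step)
      parent <- add_child(sim, parent, pos, radius = dend_r)
      disable_front(sim, parent)
      dend[i] <- parent
    }
    if (synapse_counts[k] > 0L) {
      # axon fibre: a drop from the axon soma, then a chain running parallel
      # to the dendrite 1 um above it
      over <- dir * (5 + step) + c(0, 0, z_off)
      fib <- add_child(sim, ax_soma, over + c(0, 0, 30), radius = axon_r)
      disable_front(sim, fib)
      fib <- add_child(sim, fib, over, radius = axon_r)
      disable_front(sim, fib)
      for (i in seq_len(synapse_counts[k])) {
        pos <- dir * (5 + min(i + 1, chain_len) * step) + c(0, 0, z_off)
        fib <- add_child(sim, fib, pos, radius = axon_r)
        disable_front(sim, fib)
        add_synapse(sim, pre = fib, post = dend[min(i + 1, chain_len)],
                    max_distance = 0.5)
      }
    }
    roots[k] <- dend[1L]
  }
  enable_front(sim, soma, "active")
  counts <- vapply(roots, function(r) count_synapses(sim, r, branch = TRUE), 0L)
  simulation_loop(sim, 1L)
  list(sim = sim, roots = roots, counts = counts,
       retracted = roots[sim$store$retracted[roots]])
}
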