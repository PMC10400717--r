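# Simulation engine ------------------------------------------------------------

#' Define a neuron type (front subclass)
#'
#' A neuron type pairs a name with a growth rule. The rule is called once per
#' cycle for every enabled front of the type, in the role of `manage_front`:
#' it receives the simulation object and the id of the front being processed
#' (`self`) and drives growth through [add_child()], [migrate_soma()],
#' [retract()], [retract_branch()], [enable_front()] and [disable_front()].
#' Each type is stored in its own fixed-size array row of the front store.
#'
#' @param name type name (unique within a simulation).
#' @param grow function `(sim, self)` implementing the per-front rule.
#' @param params optional list of type-level parameters, available to the
#'   rule as `sim$types[[row]]$params`.
#' @return an object of class `ng_neuron_type`.
#' @export
neuron_type <- function(name, grow, params = list()) {
  stopifnot(is.character(name), length(name) == 1L, is.function(grow))
  structure(list(name = name, grow = grow, params = params),
            class = "ng_neuron_type")
}

#' Create a simulation
#'
#' Builds the full simulation state: the fixed-capacity front store
#' partitioned into per-core private sections, the collision grid, the lock
#' tables, per-worker instruction slots and result mailboxes, and (optionally)
#' the SQLite trace database. `num_workers = 1` is serial mode -- the
#' equivalent of running on two cores, one admin plus one processing core --
#' and is the only mode with a bit-reproducibility guarantee; with more
#' workers the scheduling machinery distributes fronts across simulated
#' cores, each with its own RNG stream.
#'
#' @param volume_min,volume_max opposite corners of the simulation volume (um).
#' @param neuron_types list of [neuron_type()] objects; one front-store row
#'   is created per type.
#' @param seed integer random seed. Controls soma placement and, in serial
#'   mode, the entire trajectory.
#' @param num_workers number of simulated processing cores (`>= 1`).
#' @param db path to the SQLite trace database, or `NULL` for no storage.
#' @param grid_step lattice spacing of the collision grid (um), default 20.
#' @param block_size size of the linked blocks holding front ids per grid
#'   point, default 10.
#' @param section_size capacity of each core's private front-store section
#'   per type row. The store holds
#'   `length(neuron_types) * (num_workers + 1) * section_size` fronts.
#' @param grid_section_blocks blocks per core section of the grid id store.
#' @param lock_timeout grid-lock timeout in broker steps (the logical
#'   equivalent of the 1 s wall-clock budget).
#' @return a simulation object (an environment of class `ng_sim`).
#' @export
new_simulation <- function(volume_min, volume_max, neuron_types, seed = 1L,
                           num_workers = 1L, db = NULL, grid_step = 20,
                           block_size = 10L, section_size = 2000L,
                           grid_section_blocks = 2048L, lock_timeout = 25L) {
  stopifnot(length(volume_min) == 3L, length(volume_max) == 3L,
            num_workers >= 1L, length(neuron_types) >= 1L)
  if (inherits(neuron_types, "ng_neuron_type")) neuron_types <- list(neuron_types)
  names(neuron_types) <- vapply(neuron_types, `[[`, "", "name")
  sim <- new.env(parent = emptyenv())
  class(sim) <- "ng_sim"
  sim$volume_min <- as.numeric(volume_min)
  sim$volume_max <- as.numeric(volume_max)
  sim$types <- neuron_types
  sim$seed <- as.integer(seed)
  sim$num_workers <- as.integer(num_workers)
  sim$n_sections <- as.integer(num_workers) + 1L   # section 1 = admin
  sim$cycle <- 0L
  sim$lock_timeout <- as.integer(lock_timeout)

  sim$store <- new_front_store(length(neuron_types), sim$n_sections, section_size)
  cfg <- new_grid_config(sim$volume_min, sim$volume_max, grid_step, block_size)
  sim$grid_config <- cfg
  sim$grid <- new_grid_map(cfg, sim$n_sections, grid_section_blocks)
  sim$locks <- new_lock_state(cfg$n_gids, sim$n_sections)
  sim$fid_gids <- list()                       # fid -> registered gids

  sim$neurons <- data.frame(soma = integer(0), name = character(0),
                            type = character(0), birth_cycle = integer(0),
                            stringsAsFactors = FALSE)
  sim$synapses <- data.frame(pre = integer(0), post = integer(0),
                             weight = numeric(0), birth_cycle = integer(0),
                             death_cycle = integer(0))
  sim$firing_rate <- numeric(0)                # per neuron row
  sim$substrate <- data.frame(name = character(0), x = numeric(0),
                              y = numeric(0), z = numeric(0),
                              n_mol = numeric(0), D = numeric(0),
                              birth_cycle = integer(0), stringsAsFactors = FALSE)

  sim$current_front <- NULL                    # NotSelf enforcement context
  sim$current_pid <- 1L                        # admin by default
  sim$retract_queue <- list()
  sim$results <- replicate(num_workers, list(), simplify = FALSE)
  sim$slots <- matrix(0L, num_workers, 2L)     # per-worker instruction slots
  sim$worker_rng <- vector("list", num_workers)
  sim$dispatch_log <- list()                   # (cycle, pid, fid) audit
  sim$slot_trace <- list()                     # slot snapshots (audit mode)
  sim$gce_log <- data.frame(cycle = integer(0), pid = integer(0),
                            count = integer(0))
  sim$pending_events <- list()                 # results-style event stream
  sim$pend_fronts <- integer(0)                # uncommitted front creations
  sim$pend_neurons <- integer(0)
  sim$pend_mig <- integer(0)
  sim$pend_syn <- integer(0)
  sim$pend_sub <- integer(0)
  sim$migration_history <- data.frame(soma = integer(0), cycle = integer(0),
                                      x = numeric(0), y = numeric(0),
                                      z = numeric(0))
  sim$thick_front_warned <- FALSE

  sim$db <- NULL
  if (!is.null(db)) {
    sim$db <- trace_db_open(db, sim)
  }
  sim
}

#' @export
print.ng_sim <- function(x, ...) {
  st <- x$store
  cat(sprintf(
    "<neural development simulation>\n  cycle: %d\n  volume: [%s] - [%s] um\n  types: %s\n  workers: %d\n  fronts: %d live / %d created\n",
    x$cycle, paste(x$volume_min, collapse = ", "),
    paste(x$volume_max, collapse = ", "),
    paste(names(x$types), collapse = ", "), x$num_workers,
    length(live_fids(st)), sum(st$used)))
  invisible(x)
}

type_row <- function(sim, type) {
  row <- match(type, names(sim$types))
  if (is.na(row)) usage_error(sprintf("unknown neuron type '%s'", type))
  row
}

# Deterministic per-(seed, pid, cycle) RNG stream seed (31-bit).
stream_seed <- function(seed, pid, cycle) {
  m <- 2147483629
  s <- (as.numeric(seed) %% m) * 48271 %% m
  as.integer((s + pid * 1299721 + cycle * 7919) %% m)
}

point_in_volume <- function(sim, p, margin = 0) {
  all(p >= sim$volume_min + margin) && all(p <= sim$volume_max - margin)
}

check_radius_vs_grid <- function(sim, radius) {
  if (radius > sim$grid_config$grid_step / 2 && !sim$thick_front_warned) {
    sim$thick_front_warned <- TRUE
    warning(sprintf(
      "front radius %.2f um is >= grid_step/2 (%.2f um); collision search soundness is only guaranteed for thinner fronts -- increase grid_step",
      radius, sim$grid_config$grid_step / 2), call. = FALSE)
  }
}

record_event <- function(sim, event) {
  sim$pending_events[[length(sim$pending_events) + 1L]] <- event
  # mirror into the creating worker's results mailbox (admin consumes once)
  pid <- sim$current_pid
  if (pid >= 2L) {
    w <- pid - 1L
    sim$results[[w]][[length(sim$results[[w]]) + 1L]] <-
      list(fid = event$fid, symbol = event$symbol)
  }
  invisible(NULL)
}

# Structural exclusions for a prospective child of `parent_fid` anchored at
# `orig`: the parent itself plus existing children of the parent that share
# the same origin point (branch siblings).
candidate_exclusions <- function(store, parent_fid, orig) {
  excl <- parent_fid
  for (ch in children_of(store, parent_fid)) {
    if (sum((store$orig[ch, ] - orig)^2) < 1e-18) excl <- c(excl, ch)
  }
  excl
}

# Shared add_child/collision plumbing: acquire grid locks (parallel mode),
# run the collision query, return hit id (0 = free). Releases read locks
# before returning; preliminary write locks on `gids` are left held on
# success and must be released (or upgraded) by the caller.
locked_collision_check <- function(sim, gids, p0, p1, radius, exclude) {
  pid <- sim$current_pid
  ls <- sim$locks
  prelim <- lock_acquire_set(ls, pid, gids, "prelim", sim$lock_timeout)
  read_gids <- setdiff(
    sort(unique(unlist(lapply(gids, grid_neighbors, config = sim$grid_config)))),
    gids)
  reads <- tryCatch(
    lock_acquire_set(ls, pid, read_gids, "read", sim$lock_timeout),
    gridCompetitionError = function(e) {
      lock_release_set(ls, pid, prelim, "write")
      stop(e)
    })
  hit <- grid_collision_query(sim$grid, sim$store, p0, p1, radius, gids,
                              exclude = exclude, mode = "first")
  lock_release_set(ls, pid, reads, "read")
  if (hit != 0L) {
    lock_release_set(ls, pid, prelim, "write")
  }
  list(hit = hit, prelim = prelim)
}

#' Create a child front
#'
#' The workhorse of every growth rule: proposes a new cylindrical front with
#' distal coordinate `new_pos` as a child of `self`. The child's proximal
#' coordinate follows from the parent ([make_child_geometry()]). The call is
#' atomic -- on any failure no trace of the attempt remains -- and fails with
#' a classed condition a rule can catch: `volumeError`, `insideParentError`,
#' `collisionError` (carrying the first colliding front id),
#' `gridCompetitionError`, `overflowError`, or `notSelfError` if `self` is
#' not the front currently dispatched.
#'
#' @param sim a simulation object.
#' @param self the front being processed (the parent of the new child).
#' @param new_pos numeric length-3 end coordinate of the new front (um).
#' @param radius child radius (um); defaults to the parent's radius.
#' @param swc_type SWC structure type of the child (3 = basal dendrite).
#' @param kind `"neurite"` for ordinary growth; `"filipodium"` or `"axon"`
#'   mark the special children of a migrating soma.
#' @return the new front's id (invisibly usable like any fid).
#' @export
add_child <- function(sim, self, new_pos, radius = NULL, swc_type = 3L,
                      kind = c("neurite", "filipodium", "axon")) {
  kind <- match.arg(kind)
  st <- sim$store
  if (!is.null(sim$current_front) && sim$current_front != self) {
    not_self_error()
  }
  if (!st$used[self] || st$retracted[self]) {
    usage_error("add_child: parent front is not live")
  }
  if (!point_in_volume(sim, new_pos)) volume_error()
  if (is.null(radius)) radius <- st$radius[self]
  if (radius <= 0) usage_error("add_child: radius must be positive")
  check_radius_vs_grid(sim, radius)
  if (kind == "filipodium" && st$filipodium[self] != 0L) {
    usage_error("soma already has a filipodium")
  }

  geom <- make_child_geometry(sim, self, new_pos)  # may raise insideParent
  gids <- front_to_gids(sim$grid_config, geom$orig, geom$end)
  exclude <- candidate_exclusions(st, self, geom$orig)
  chk <- locked_collision_check(sim, gids, geom$orig, geom$end, radius, exclude)
  if (chk$hit != 0L) collision_error(chk$hit)

  pid <- sim$current_pid
  ls <- sim$locks
  row <- fid_row(st, self)
  child <- tryCatch(
    store_allocate(st, pid, row, names(sim$types)[row]),
    overflowError = function(e) {
      lock_release_set(ls, pid, chk$prelim, "write")
      stop(e)
    })

  # write the record before linking; grid registration under full locks
  st$used[child] <- TRUE
  st$shape[child] <- SHAPE_CYLINDER
  st$orig[child, ] <- geom$orig
  st$end[child, ] <- geom$end
  st$radius[child] <- radius
  st$birth_cycle[child] <- sim$cycle
  st$death_cycle[child] <- NA_integer_
  st$swc_type[child] <- as.integer(swc_type)

  reg_ok <- tryCatch({
    full <- lock_acquire_set(ls, pid, gids, "full", sim$lock_timeout)
    for (g in gids) grid_register(sim$grid, pid, g, child)
    lock_release_set(ls, pid, gids, "write")
    TRUE
  }, ng_error = function(e) e)
  if (!isTRUE(reg_ok)) {
    st$used[child] <- FALSE
    store_rollback(st, pid, row)
    lock_release_set(ls, pid, chk$prelim, "write")
    stop(reg_ok)
  }
  sim$fid_gids[[as.character(child)]] <- gids

  attach_child(st, self, child)
  st$status[child] <- STATUS_GROWING
  if (kind == "filipodium") {
    st$filipodium[self] <- child
    st$has_filipodium[self] <- TRUE
    st$swc_type[child] <- 12L
  } else if (kind == "axon") {
    st$has_trailing_axon[self] <- TRUE
    st$axon_tip[self] <- child
    st$swc_type[child] <- 2L
  }
  sim$pend_fronts <- c(sim$pend_fronts, child)
  record_event(sim, list(symbol = "created", fid = child))
  child
}

#' Add somata to the simulation
#'
#' Creates `n` collision-checked spherical somata of the given type, placed
#' explicitly, on a regular grid, or uniformly at random inside a box. Somata
#' are allocated in the admin core's private store section and scheduled as
#' growing fronts for the next cycle. The simulation seed determines random
#' placement.
#'
#' @param sim a simulation object.
#' @param type neuron type name (must be registered in the simulation).
#' @param name base neuron name; neurons are named `name_1`, `name_2`, ...
#' @param n number of somata (ignored for explicit `positions`).
#' @param soma_radius soma radius (um).
#' @param placement `"random"`, `"grid"`, or `"explicit"`.
#' @param box for random/grid placement: list with `min` and `max` corners;
#'   defaults to the whole volume inset by the soma radius.
#' @param positions for explicit placement: a matrix of soma centres (n x 3).
#' @param max_tries retry budget per random placement.
#' @return integer vector of soma front ids.
#' @export
add_neurons <- function(sim, type, name, n = 1L, soma_radius = 10,
                        placement = c("random", "grid", "explicit"),
                        box = NULL, positions = NULL, max_tries = 100L) {
  placement <- match.arg(placement)
  row <- type_row(sim, type)
  st <- sim$store
  check_radius_vs_grid(sim, soma_radius)
  if (placement == "explicit") {
    stopifnot(!is.null(positions))
    positions <- matrix(as.numeric(positions), ncol = 3L)
    n <- nrow(positions)
  }
  if (is.null(box)) {
    box <- list(min = sim$volume_min + soma_radius,
                max = sim$volume_max - soma_radius)
  }
  old_rng <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(stream_seed(sim$seed, 1L, sim$cycle))
  on.exit({
    if (!is.null(old_rng)) assign(".Random.seed", old_rng, globalenv())
  })

  if (placement == "grid") {
    k <- ceiling(n^(1 / 3))
    gx <- seq(box$min[1], box$max[1], length.out = max(k, 2L))
    gy <- seq(box$min[2], box$max[2], length.out = max(k, 2L))
    gz <- seq(box$min[3], box$max[3], length.out = max(k, 2L))
    grid_pos <- as.matrix(expand.grid(gx, gy, gz))[seq_len(n), , drop = FALSE]
  }

  out <- integer(n)
  for (i in seq_len(n)) {
    tries <- if (placement == "random") max_tries else 1L
    created <- 0L
    last_err <- NULL
    for (tr in seq_len(tries)) {
      pos <- switch(placement,
        random = stats::runif(3L, box$min, box$max),
        grid = grid_pos[i, ],
        explicit = positions[i, ])
      created <- tryCatch(
        add_soma(sim, row, pos, soma_radius),
        collisionError = function(e) { last_err <<- e; 0L })
      if (created != 0L) break
    }
    if (created == 0L) stop(last_err)
    out[i] <- created
    sim$neurons <- rbind(sim$neurons, data.frame(
      soma = created, name = sprintf("%s_%d", name, i), type = type,
      birth_cycle = sim$cycle, stringsAsFactors = FALSE))
    sim$firing_rate <- c(sim$firing_rate, 0)
    sim$pend_neurons <- c(sim$pend_neurons, nrow(sim$neurons))
  }
  out
}

# Create one collision-checked soma (admin context, pid 1).
add_soma <- function(sim, row, pos, radius) {
  st <- sim$store
  if (!point_in_volume(sim, pos, margin = radius)) volume_error()
  gids <- front_to_gids(sim$grid_config, pos, pos)
  hit <- grid_collision_query(sim$grid, st, pos, pos, radius, gids,
                              exclude = integer(0), mode = "first")
  if (hit != 0L) collision_error(hit)
  fid <- store_allocate(st, 1L, row, names(sim$types)[row])
  st$used[fid] <- TRUE
  st$shape[fid] <- SHAPE_SPHERE
  st$orig[fid, ] <- pos
  st$end[fid, ] <- pos
  st$radius[fid] <- radius
  st$order[fid] <- 0L
  st$path_length[fid] <- 0
  st$soma[fid] <- fid
  st$status[fid] <- STATUS_GROWING
  st$birth_cycle[fid] <- sim$cycle
  st$death_cycle[fid] <- NA_integer_
  st$swc_type[fid] <- 1L
  for (g in gids) grid_register(sim$grid, 1L, g, fid)
  sim$fid_gids[[as.character(fid)]] <- gids
  old_pid <- sim$current_pid
  sim$current_pid <- 1L
  record_event(sim, list(symbol = "created", fid = fid))
  sim$current_pid <- old_pid
  sim$pend_fronts <- c(sim$pend_fronts, fid)
  fid
}

#' Migrate a soma
#'
#' Moves a soma to `new_pos`, subject to collision detection against
#' everything except the soma's own filipodium and trailing-axon chain.
#' Migration is only allowed while the soma has no dendrites: its children
#' may only be one filipodium and the trailing-axon tip. If a trailing axon
#' is enabled, a new axon front spanning the displacement is automatically
#' created behind the soma; an existing filipodium keeps its distal tip and
#' is re-anchored on the new soma surface.
#'
#' @param sim a simulation object.
#' @param self the migrating soma (must be the dispatched front).
#' @param new_pos numeric length-3 new soma centre (um).
#' @return the soma id, invisibly.
#' @export
migrate_soma <- function(sim, self, new_pos) {
  st <- sim$store
  if (!is.null(sim$current_front) && sim$current_front != self) not_self_error()
  if (st$shape[self] != SHAPE_SPHERE) usage_error("migrate_soma: not a soma")
  kids <- children_of(st, self)
  allowed <- c(st$filipodium[self],
               if (st$has_trailing_axon[self]) kids[st$swc_type[kids] == 2L])
  if (length(setdiff(kids, allowed))) {
    usage_error("migrate_soma: soma already has dendrites")
  }
  if (!point_in_volume(sim, new_pos, margin = st$radius[self])) volume_error()

  old_pos <- st$orig[self, ]
  subtree <- collect_branch(st, self)          # ignore own filipodium/axon
  gids_new <- front_to_gids(sim$grid_config, new_pos, new_pos)
  chk <- locked_collision_check(sim, gids_new, new_pos, new_pos,
                                st$radius[self], exclude = subtree)
  if (chk$hit != 0L) collision_error(chk$hit)

  pid <- sim$current_pid
  ls <- sim$locks
  gids_old <- sim$fid_gids[[as.character(self)]]
  move_ok <- tryCatch({
    full <- lock_acquire_set(ls, pid, gids_new, "full", sim$lock_timeout)
    for (g in gids_old) grid_deregister(sim$grid, g, self)
    st$orig[self, ] <- new_pos
    st$end[self, ] <- new_pos
    for (g in gids_new) grid_register(sim$grid, pid, g, self)
    lock_release_set(ls, pid, gids_new, "write")
    TRUE
  }, ng_error = function(e) e)
  if (!isTRUE(move_ok)) {
    lock_release_set(ls, pid, chk$prelim, "write")
    stop(move_ok)
  }
  sim$fid_gids[[as.character(self)]] <- gids_new

  # trailing axon: one new front spanning the displacement
  if (st$has_trailing_axon[self] && st$axon_tip[self] != 0L) {
    tip <- st$axon_tip[self]
    a_orig <- st$end[tip, ]
    a_end <- a_orig + (new_pos - old_pos)
    ax <- tryCatch(store_allocate(st, pid, fid_row(st, self)),
                   overflowError = function(e) stop(e))
    st$used[ax] <- TRUE
    st$shape[ax] <- SHAPE_CYLINDER
    st$orig[ax, ] <- a_orig
    st$end[ax, ] <- a_end
    st$radius[ax] <- st$radius[tip]
    st$birth_cycle[ax] <- sim$cycle
    st$death_cycle[ax] <- NA_integer_
    st$swc_type[ax] <- 2L
    ax_gids <- front_to_gids(sim$grid_config, a_orig, a_end)
    for (g in ax_gids) grid_register(sim$grid, pid, g, ax)
    sim$fid_gids[[as.character(ax)]] <- ax_gids
    attach_child(st, tip, ax)
    st$status[ax] <- STATUS_DISABLED
    st$axon_tip[self] <- ax
    sim$pend_fronts <- c(sim$pend_fronts, ax)
    record_event(sim, list(symbol = "created", fid = ax))
  }

  # filipodium keeps its tip; its origin moves to the new soma surface
  fil <- st$filipodium[self]
  if (fil != 0L) {
    tip_end <- st$end[fil, ]
    d <- tip_end - new_pos
    len <- norm3(d)
    if (len > st$radius[self]) {
      new_orig <- new_pos + d / len * st$radius[self]
      old_fil_gids <- sim$fid_gids[[as.character(fil)]]
      for (g in old_fil_gids) grid_deregister(sim$grid, g, fil)
      st$orig[fil, ] <- new_orig
      st$path_length[fil] <- st$radius[self] + norm3(tip_end - new_orig)
      fil_gids <- front_to_gids(sim$grid_config, new_orig, tip_end)
      for (g in fil_gids) grid_register(sim$grid, pid, g, fil)
      sim$fid_gids[[as.character(fil)]] <- fil_gids
    }
  }

  sim$migration_history <- rbind(sim$migration_history, data.frame(
    soma = self, cycle = sim$cycle,
    x = new_pos[1], y = new_pos[2], z = new_pos[3]))
  sim$pend_mig <- c(sim$pend_mig, nrow(sim$migration_history))
  record_event(sim, list(symbol = "migrated", fid = self))
  invisible(self)
}

#' Retract fronts
#'
#' `retract()` schedules the removal of a single terminal front;
#' `retract_branch()` schedules an entire branch (the given child of `self`
#' plus all its descendants). Removals are queued and applied serially by the
#' admin at the end of the cycle: only then are flags set, grid entries
#' deregistered, child lists updated, and deaths recorded -- growth elsewhere
#' in the same cycle still sees the old structure.
#'
#' @param sim a simulation object.
#' @param self the front being processed.
#' @param child for `retract_branch()`: the child of `self` rooting the
#'   branch to remove; defaults to `self`'s whole subtree when `self` is the
#'   dispatched front and has a parent.
#' @return invisibly, the ids scheduled for removal.
#' @export
retract <- function(sim, self) {
  st <- sim$store
  if (!is.null(sim$current_front) && sim$current_front != self) not_self_error()
  if (st$retracted[self]) usage_error("front is already retracted")
  if (st$num_children[self] != 0L) {
    usage_error("retract: only terminal fronts can be retracted singly")
  }
  queue_retraction(sim, self)
}

#' @rdname retract
#' @export
retract_branch <- function(sim, self, child = NULL) {
  st <- sim$store
  if (!is.null(sim$current_front) && sim$current_front != self) not_self_error()
  if (is.null(child)) child <- self
  if (child != self && st$parent[child] != self) {
    usage_error("retract_branch: child is not a child of self")
  }
  if (st$retracted[child]) usage_error("front is already retracted")
  queue_retraction(sim, collect_branch(st, child))
}

queue_retraction <- function(sim, fids) {
  queued <- unlist(lapply(sim$retract_queue, `[[`, "fids"))
  if (length(intersect(fids, queued))) {
    usage_error("front already scheduled for retraction this cycle")
  }
  sim$retract_queue[[length(sim$retract_queue) + 1L]] <-
    list(fids = fids, cycle = sim$cycle)
  record_event(sim, list(symbol = "retract_scheduled", fid = fids[1L]))
  invisible(fids)
}

# Applied by the admin at end of cycle, serially.
apply_retractions <- function(sim) {
  st <- sim$store
  retracted <- integer(0)
  for (req in sim$retract_queue) {
    for (fid in req$fids) {
      if (st$retracted[fid]) next
      mark_retracted(st, fid, sim$cycle)
      key <- as.character(fid)
      for (g in sim$fid_gids[[key]]) grid_deregister(sim$grid, g, fid)
      sim$fid_gids[[key]] <- NULL
      # a retracted filipodium frees its soma
      soma <- st$soma[fid]
      if (soma != 0L && st$filipodium[soma] == fid) {
        st$filipodium[soma] <- 0L
        st$has_filipodium[soma] <- FALSE
      }
      retracted <- c(retracted, fid)
    }
  }
  if (length(retracted) && nrow(sim$synapses)) {
    gone <- (sim$synapses$pre %in% retracted | sim$synapses$post %in% retracted) &
      is.na(sim$synapses$death_cycle)
    sim$synapses$death_cycle[gone] <- sim$cycle
    sim$pend_syn <- c(sim$pend_syn, which(gone))
  }
  sim$retract_queue <- list()
  retracted
}

#' Try to overcome a collision automatically
#'
#' After a failed [add_child()] ending in a `collisionError`, proposes up to
#' eight alternative positions at the same step length, angularly deflected
#' away from the colliding front, and returns the first collision-free one,
#' or `NULL` when all candidates collide (e.g. a fully enclosed tip).
#'
#' @param sim a simulation object.
#' @param self the front that attempted to grow.
#' @param failed_pos the position that collided.
#' @param colliding optionally, the colliding front id from the
#'   `collisionError`; used to orient the deflection away from the obstacle.
#' @return a length-3 position, or `NULL` on failure.
#' @export
solve_collision <- function(sim, self, failed_pos, colliding = NULL) {
  st <- sim$store
  anchor <- if (st$shape[self] == SHAPE_SPHERE) st$orig[self, ] else st$end[self, ]
  d <- failed_pos - anchor
  len <- norm3(d)
  if (len == 0) return(NULL)
  dhat <- d / len
  # deflection basis: e1 points away from the obstacle when known
  e1 <- NULL
  if (!is.null(colliding) && colliding != 0L && st$used[colliding]) {
    ax <- front_axis(st, colliding)
    away <- anchor - (ax$p0 + ax$p1) / 2
    away <- away - sum(away * dhat) * dhat
    if (norm3(away) > 1e-9) e1 <- away / norm3(away)
  }
  if (is.null(e1)) {
    ref <- if (abs(dhat[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- cross3(dhat, ref); e1 <- e1 / norm3(e1)
  }
  e2 <- cross3(dhat, e1)
  cands <- list(c(30, 1), c(-30, 1), c(60, 1), c(-60, 1),
                c(30, 2), c(-30, 2), c(60, 2), c(-60, 2))
  for (cd in cands) {
    ang <- abs(cd[1]) * pi / 180
    ee <- if (cd[2] == 1) e1 else e2
    dir <- cos(ang) * dhat + sin(ang) * sign(cd[1]) * ee
    pos <- anchor + dir / norm3(dir) * len
    free <- tryCatch({
      geom <- make_child_geometry(sim, self, pos)
      if (!point_in_volume(sim, pos)) FALSE
      else {
        gids <- front_to_gids(sim$grid_config, geom$orig, geom$end)
        hit <- grid_collision_query(
          sim$grid, st, geom$orig, geom$end, st$radius[self], gids,
          exclude = candidate_exclusions(st, self, geom$orig), mode = "first")
        hit == 0L
      }
    }, ng_error = function(e) FALSE)
    if (isTRUE(free)) return(pos)
  }
  NULL
}

#' Close a simulation
#'
#' Flushes and closes the trace database. Call once at the end of a run
#' (the equivalent of the destruction step that shuts down worker processes).
#'
#' @param sim a simulation object.
#' @return `NULL`, invisibly.
#' @export
finalize_simulation <- function(sim) {
  if (!is.null(sim$db)) {
    DBI::dbDisconnect(sim$db)
    sim$db <- NULL
  }
  invisible(NULL)
}
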