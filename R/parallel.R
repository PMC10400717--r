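# Cycle loop and shared-memory style scheduling --------------------------------
#
# The cycle machinery realises the shared-memory parallel design as a
# deterministic cooperative step machine: simulated workers (cores 2..N+1)
# with private store sections, two instruction slots and a results mailbox
# each, an admin (core 1) that schedules fronts and consumes results, and the
# serial lock broker arbitrating grid access. With one worker this reduces
# exactly to the reproducible serial engine; with several, fronts are
# interleaved across workers, each drawing from its own (seed, pid, cycle)
# RNG stream, so individual runs differ while the grown morphologies are
# statistically equivalent.

SENTINEL_FID <- -1L

worker_pid <- function(w) w + 1L

# Swap a worker's RNG stream into the session, run fn, swap back out.
with_worker_rng <- function(sim, w, fn) {
  had <- exists(".Random.seed", globalenv())
  outer_rng <- if (had) get(".Random.seed", globalenv()) else NULL
  if (is.null(sim$worker_rng[[w]])) {
    set.seed(stream_seed(sim$seed, worker_pid(w), sim$cycle))
  } else {
    assign(".Random.seed", sim$worker_rng[[w]], globalenv())
  }
  on.exit({
    sim$worker_rng[[w]] <- get(".Random.seed", globalenv())
    if (had) assign(".Random.seed", outer_rng, globalenv())
  })
  fn()
}

# Cached gids of a live front's current geometry (registered set).
sched_gids <- function(sim, fid) {
  g <- sim$fid_gids[[as.character(fid)]]
  if (is.null(g)) integer(0) else g
}

# Admin: place front in a worker slot after setting preliminary write locks
# on all its grid points (holder = the worker that will process it).
sched_assign <- function(sim, w, fid) {
  pid <- worker_pid(w)
  gids <- sched_gids(sim, fid)
  sim$locks$write_lock[gids] <- pid
  for (g in gids) lock_log(sim$locks, pid, g, "prelim", "grant")
  free <- which(sim$slots[w, ] == 0L)[1L]
  sim$slots[w, free] <- fid
  invisible(NULL)
}

# A front is schedulable if none of its gids is already write-locked.
sched_conflict_free <- function(sim, fid) {
  gids <- sched_gids(sim, fid)
  all(sim$locks$write_lock[gids] == 0L)
}

# One worker step: consume the first instruction slot (clearing it before
# processing, which is the "processing has started" signal), run the growth
# rule under the worker's RNG stream, then release the scheduling locks.
worker_step <- function(sim, w) {
  fid <- sim$slots[w, 1L]
  if (fid == 0L) return(FALSE)
  sim$slots[w, 1L] <- sim$slots[w, 2L]         # shift the 2-slot queue
  sim$slots[w, 2L] <- 0L
  if (fid == SENTINEL_FID) {
    sim$worker_done[w] <- TRUE
    return(TRUE)
  }
  pid <- worker_pid(w)
  sim$dispatch_log[[length(sim$dispatch_log) + 1L]] <-
    list(cycle = sim$cycle, pid = pid, fid = fid)
  sched_locked <- sched_gids(sim, fid)         # before the rule moves anything
  st <- sim$store
  if (st$used[fid] && !st$retracted[fid] && st$status[fid] != STATUS_DISABLED) {
    row <- fid_row(st, fid)
    grow <- sim$types[[row]]$grow
    sim$current_front <- fid
    sim$current_pid <- pid
    with_worker_rng(sim, w, function() {
      tryCatch(grow(sim, fid), ng_error = function(e) {
        # a simulation error escaping the rule is recorded, not fatal
        sim$results[[w]][[length(sim$results[[w]]) + 1L]] <-
          list(fid = fid, symbol = paste0("failed:", class(e)[1L]))
      })
    })
    sim$current_front <- NULL
    sim$current_pid <- 1L
  }
  # release this front's scheduling locks (those still held)
  lock_release_set(sim$locks, pid, sched_locked, "write")
  TRUE
}

# Scheduling order: growing fronts first, then migrating, then other active
# fronts, ascending id within each category.
cycle_backlog <- function(sim) {
  st <- sim$store
  live <- st$used & !st$retracted
  c(sort(which(live & st$status == STATUS_GROWING)),
    sort(which(live & st$status == STATUS_MIGRATING)),
    sort(which(live & st$status == STATUS_ACTIVE)))
}

# Run one cycle: schedule/refill instruction slots, step workers round-robin
# until backlog and slots drain, send sentinels, then do the serial admin
# work (retractions, storage, mailbox consumption).
run_cycle <- function(sim, plan = NULL) {
  sim$cycle <- sim$cycle + 1L
  W <- sim$num_workers
  sim$worker_done <- rep(FALSE, W)
  sim$worker_rng <- vector("list", W)
  gce_before <- sim$locks$gce

  if (!is.null(plan)) {
    # scripted dispatch (one (fid, worker) pair at a time, in order)
    for (i in seq_along(plan$fid)) {
      w <- plan$worker[i]
      sched_assign(sim, w, plan$fid[i])
      worker_step(sim, w)
    }
  } else {
    backlog <- cycle_backlog(sim)
    repeat {
      # refill: two ids per worker while the backlog is large, one near
      # exhaustion; skip (defer) fronts on write-locked grid points
      target <- if (length(backlog) > W) 2L else 1L
      for (w in seq_len(W)) {
        while (sum(sim$slots[w, ] != 0L) < target && length(backlog)) {
          ok <- which(vapply(backlog, sched_conflict_free, TRUE, sim = sim))
          if (!length(ok)) break
          fid <- backlog[ok[1L]]
          backlog <- backlog[-ok[1L]]
          sched_assign(sim, w, fid)
        }
      }
      if (sim$locks$audit) {
        # audit trail: who is resident in which slot after every refill
        sim$slot_trace[[length(sim$slot_trace) + 1L]] <- sim$slots
      }
      any_step <- FALSE
      for (w in seq_len(W)) {
        if (worker_step(sim, w)) any_step <- TRUE
      }
      if (!length(backlog) && all(sim$slots == 0L)) break
      if (!any_step && length(backlog) && all(sim$slots == 0L)) {
        # every remaining front sits on write-locked grid points with no
        # worker left to release them; deferral cannot make progress, so
        # dispatch the head of the backlog anyway
        fid <- backlog[1L]
        backlog <- backlog[-1L]
        sched_assign(sim, 1L, fid)
        worker_step(sim, 1L)
      }
    }
    # end-of-cycle sentinels
    for (w in seq_len(W)) {
      sim$slots[w, 1L] <- SENTINEL_FID
      worker_step(sim, w)
    }
  }

  # ---- serial admin phase ----
  retracted <- apply_retractions(sim)
  persist_cycle(sim, retracted)
  # per-cycle GridCompetition counters per worker
  delta <- sim$locks$gce - gce_before
  hit <- which(delta > 0)
  if (length(hit)) {
    sim$gce_log <- rbind(sim$gce_log, data.frame(
      cycle = sim$cycle, pid = hit, count = delta[hit]))
  }
  sim$results <- replicate(W, list(), simplify = FALSE)  # consumed
  invisible(sim)
}

#' Run the simulation for a number of cycles
#'
#' Advances the clock cycle by cycle. Each cycle every enabled front is
#' dispatched exactly once -- growing fronts first, then migrating, then
#' other active fronts -- and its growth rule may create children, migrate,
#' or schedule retractions. Retractions are applied serially at the end of
#' the cycle, after which the cycle's events are committed to the trace
#' database. The loop may be called repeatedly, e.g. to add neurons between
#' growth phases.
#'
#' @param sim a simulation object.
#' @param n_cycles number of cycles to run (`>= 0`).
#' @param dispatch_plan optional scripted dispatch for a single cycle batch:
#'   a list of per-cycle lists with integer vectors `fid` and `worker`,
#'   processed in the given order. Intended for deterministic replay of
#'   worked scheduling examples; `NULL` (default) uses the normal scheduler.
#' @return the simulation object, invisibly.
#' @export
simulation_loop <- function(sim, n_cycles, dispatch_plan = NULL) {
  stopifnot(n_cycles >= 0)
  for (i in seq_len(n_cycles)) {
    plan <- if (!is.null(dispatch_plan) && i <= length(dispatch_plan)) {
      dispatch_plan[[i]]
    } else NULL
    run_cycle(sim, plan)
  }
  invisible(sim)
}

#' Grid-competition diagnostics
#'
#' Summarises the per-cycle GridCompetition counters collected during the
#' run: for each cycle, how many errors occurred, the fraction of workers
#' that saw at least one, and the mean number of errors per worker.
#'
#' @param sim a simulation object.
#' @return a `data.frame` with columns `cycle`, `total`, `frac_workers`,
#'   `mean_per_worker`.
#' @export
competition_stats <- function(sim) {
  if (!nrow(sim$gce_log)) {
    return(data.frame(cycle = integer(0), total = integer(0),
                      frac_workers = numeric(0), mean_per_worker = numeric(0)))
  }
  agg <- split(sim$gce_log, sim$gce_log$cycle)
  do.call(rbind, lapply(agg, function(d) data.frame(
    cycle = d$cycle[1L],
    total = sum(d$count),
    frac_workers = length(unique(d$pid)) / sim$num_workers,
    mean_per_worker = sum(d$count) / sim$num_workers)))
}
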