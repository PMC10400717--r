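# Grid lock broker -------------------------------------------------------------
#
# Access to the collision grid is arbitrated per grid point (gid) through two
# lock tables and two request tables:
#
#   read_lock[gid]  : 0 = free, pid = held for reading by that core
#   write_lock[gid] : 0 = free, pid = preliminary write lock, -pid = full
#   rlock_request[pid], wlock_request[pid] : 0 = none, gid = read/preliminary
#                     request, -gid = upgrade-to-full request
#
# Only the broker writes grants into the lock tables; holders release by
# zeroing their own entry. Writing is two-stage: a preliminary lock announces
# intent (reads are still allowed), a full lock excludes everything while the
# actual write happens. The broker runs serially, interleaved with the
# admin's work, so granting is race-free by construction. A requester that
# cannot obtain its lock within the timeout raises gridCompetitionError.

new_lock_state <- function(n_gids, n_sections) {
  ls <- new.env(parent = emptyenv())
  ls$read_lock <- integer(n_gids)
  ls$write_lock <- integer(n_gids)
  ls$rlock_request <- integer(n_sections)
  ls$wlock_request <- integer(n_sections)
  ls$step <- 0L                                # logical clock
  ls$audit <- FALSE                            # record grant/release trail?
  ls$log <- list()                             # grant/release audit trail
  ls$gce <- integer(n_sections)                # per-pid GridCompetition count
  ls
}

lock_log <- function(ls, pid, gid, mode, action) {
  if (!ls$audit) return(invisible(NULL))
  ls$log[[length(ls$log) + 1L]] <-
    list(step = ls$step, pid = pid, gid = gid, mode = mode, action = action)
}

#' @keywords internal
lock_broker_step <- function(ls) {
  ls$step <- ls$step + 1L
  for (pid in seq_along(ls$rlock_request)) {
    gid <- ls$rlock_request[pid]
    if (gid > 0L) {
      if (ls$read_lock[gid] == pid) {          # re-entrant: already held
        ls$rlock_request[pid] <- 0L
      } else if (ls$read_lock[gid] == 0L && ls$write_lock[gid] >= 0L) {
        # free, and not under full write lock (preliminary is fine)
        ls$read_lock[gid] <- pid
        ls$rlock_request[pid] <- 0L
        lock_log(ls, pid, gid, "read", "grant")
      }
    }
  }
  for (pid in seq_along(ls$wlock_request)) {
    req <- ls$wlock_request[pid]
    if (req > 0L) {                            # preliminary request
      gid <- req
      if (ls$write_lock[gid] == pid) {         # re-entrant
        ls$wlock_request[pid] <- 0L
      } else if (ls$write_lock[gid] == 0L) {
        ls$write_lock[gid] <- pid
        ls$wlock_request[pid] <- 0L
        lock_log(ls, pid, gid, "prelim", "grant")
      }
    } else if (req < 0L) {                     # upgrade to full
      gid <- -req
      if (ls$write_lock[gid] == -pid) {        # re-entrant
        ls$wlock_request[pid] <- 0L
      } else if (ls$write_lock[gid] == pid && ls$read_lock[gid] == 0L) {
        # only the preliminary holder may upgrade, and pending reads must
        # have drained: a full lock excludes readers entirely
        ls$write_lock[gid] <- -pid
        ls$wlock_request[pid] <- 0L
        lock_log(ls, pid, gid, "full", "grant")
      }
    }
  }
  invisible(ls)
}

lock_release <- function(ls, pid, gid, mode = c("read", "write")) {
  mode <- match.arg(mode)
  if (mode == "read") {
    if (ls$read_lock[gid] == pid) {
      ls$read_lock[gid] <- 0L
      lock_log(ls, pid, gid, "read", "release")
    }
  } else {
    if (ls$write_lock[gid] == pid || ls$write_lock[gid] == -pid) {
      held_full <- ls$write_lock[gid] < 0L
      ls$write_lock[gid] <- 0L
      lock_log(ls, pid, gid, if (held_full) "full" else "prelim", "release")
    }
  }
  invisible(ls)
}

# Request a lock and poll, driving the broker between polls (the broker runs
# interleaved with admin work; in this engine the requester's poll loop is
# where that interleaving happens). The timeout is counted in broker steps --
# a logical clock standing in for the wall-clock budget -- so timeout
# behaviour is deterministic. Returns a small status list; `owned_before`
# distinguishes re-entrant grants so callers release only locks they
# actually acquired.
lock_acquire <- function(ls, pid, gid, mode = c("read", "prelim", "full"),
                         timeout_steps = 25L) {
  mode <- match.arg(mode)
  owned_before <- switch(mode,
    read = ls$read_lock[gid] == pid,
    prelim = ls$write_lock[gid] == pid,
    full = ls$write_lock[gid] == -pid)
  if (owned_before) return(list(ok = TRUE, owned_before = TRUE))
  if (mode == "read") ls$rlock_request[pid] <- gid
  else if (mode == "prelim") ls$wlock_request[pid] <- gid
  else ls$wlock_request[pid] <- -gid
  for (i in seq_len(timeout_steps)) {
    lock_broker_step(ls)
    granted <- switch(mode,
      read = ls$read_lock[gid] == pid,
      prelim = ls$write_lock[gid] == pid,
      full = ls$write_lock[gid] == -pid)
    if (granted) return(list(ok = TRUE, owned_before = FALSE))
  }
  # timed out: withdraw the request
  if (mode == "read") ls$rlock_request[pid] <- 0L else ls$wlock_request[pid] <- 0L
  list(ok = FALSE, owned_before = FALSE)
}

# Acquire a set of gids in one mode; on any failure release what this call
# acquired and signal gridCompetitionError. Returns the gids actually
# acquired here (not re-entrant holds) for later release.
lock_acquire_set <- function(ls, pid, gids, mode, timeout_steps = 25L) {
  acquired <- integer(0)
  for (g in gids) {
    res <- lock_acquire(ls, pid, g, mode, timeout_steps)
    if (!res$ok) {
      for (h in acquired) {
        lock_release(ls, pid, h, if (mode == "read") "read" else "write")
      }
      ls$gce[pid] <- ls$gce[pid] + 1L
      grid_competition_error(g)
    }
    if (!res$owned_before) acquired <- c(acquired, g)
  }
  acquired
}

lock_release_set <- function(ls, pid, gids, mode) {
  for (g in gids) lock_release(ls, pid, g, mode)
  invisible(NULL)
}
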