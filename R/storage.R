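# Trace database and SWC export -------------------------------------------------
#
# Event-sourced SQLite trace: one transaction per cycle. Creations insert
# rows, retractions set death_cycle (rows are never deleted, mirroring the
# in-memory "flagged as retracted" rule), migrations append to a history
# table. The recorded events are sufficient to reconstruct the state at the
# last committed cycle, which is what import/resume does.

SCHEMA_VERSION <- 1L

trace_db_open <- function(path, sim) {
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  DBI::dbExecute(con, "PRAGMA journal_mode = MEMORY")
  DBI::dbExecute(con, "CREATE TABLE IF NOT EXISTS meta (key TEXT PRIMARY KEY, value TEXT)")
  DBI::dbExecute(con, "CREATE TABLE IF NOT EXISTS neuron_types (row INTEGER PRIMARY KEY, name TEXT)")
  DBI::dbExecute(con, "CREATE TABLE IF NOT EXISTS neurons (soma INTEGER PRIMARY KEY, name TEXT, type TEXT, birth_cycle INTEGER)")
  DBI::dbExecute(con, paste(
    "CREATE TABLE IF NOT EXISTS fronts (fid INTEGER PRIMARY KEY, row INTEGER,",
    "idx INTEGER, parent INTEGER, soma INTEGER, shape INTEGER,",
    "orig_x REAL, orig_y REAL, orig_z REAL, end_x REAL, end_y REAL, end_z REAL,",
    "radius REAL, ord INTEGER, path_length REAL, status INTEGER,",
    "birth_cycle INTEGER, death_cycle INTEGER, swc_type INTEGER,",
    "filipodium INTEGER, axon_tip INTEGER, has_trailing_axon INTEGER)"))
  DBI::dbExecute(con, "CREATE TABLE IF NOT EXISTS migration_history (soma INTEGER, cycle INTEGER, x REAL, y REAL, z REAL)")
  DBI::dbExecute(con, "CREATE TABLE IF NOT EXISTS synapses (id INTEGER PRIMARY KEY, pre INTEGER, post INTEGER, weight REAL, birth_cycle INTEGER, death_cycle INTEGER)")
  DBI::dbExecute(con, "CREATE TABLE IF NOT EXISTS substrate (id INTEGER PRIMARY KEY, name TEXT, x REAL, y REAL, z REAL, n_mol REAL, D REAL, birth_cycle INTEGER)")
  DBI::dbExecute(con, "CREATE TABLE IF NOT EXISTS attributes (fid INTEGER, cycle INTEGER, name TEXT, value REAL)")
  meta <- list(
    schema_version = SCHEMA_VERSION, seed = sim$seed,
    volume_min = paste(sim$volume_min, collapse = ","),
    volume_max = paste(sim$volume_max, collapse = ","),
    grid_step = sim$grid_config$grid_step,
    block_size = sim$grid_config$block_size,
    section_size = sim$store$section_size,
    num_workers = sim$num_workers, cycle = sim$cycle)
  for (k in names(meta)) {
    DBI::dbExecute(con, "INSERT OR REPLACE INTO meta VALUES (?, ?)",
                   params = list(k, as.character(meta[[k]])))
  }
  for (r in seq_along(sim$types)) {
    DBI::dbExecute(con, "INSERT OR REPLACE INTO neuron_types VALUES (?, ?)",
                   params = list(r, names(sim$types)[r]))
  }
  con
}

# Commit one cycle's events in a single transaction. Pending sets are filled
# by the creation sites and drained here, so events raised between loop
# calls (e.g. neurons added before the first cycle) are committed too.
persist_cycle <- function(sim, retracted = integer(0)) {
  sim$pending_events <- list()
  con <- sim$db
  if (is.null(con)) {
    sim$pend_fronts <- integer(0); sim$pend_neurons <- integer(0)
    sim$pend_mig <- integer(0); sim$pend_syn <- integer(0)
    sim$pend_sub <- integer(0)
    return(invisible(NULL))
  }
  st <- sim$store
  cyc <- sim$cycle
  DBI::dbExecute(con, "BEGIN")
  ok <- tryCatch({
    for (i in unique(sim$pend_neurons)) {
      DBI::dbExecute(con,
        "INSERT OR REPLACE INTO neurons VALUES (?, ?, ?, ?)",
        params = unname(as.list(sim$neurons[i, c("soma", "name", "type", "birth_cycle")])))
    }
    created <- sort(unique(sim$pend_fronts))
    created <- created[st$used[created]]
    for (fid in created) {
      DBI::dbExecute(con, paste(
        "INSERT INTO fronts VALUES",
        "(?,?,?,?,?,?,?,?,?,?,?,?,?,?,?,?,?,?,?,?,?,?)"),
        params = list(fid, fid_row(st, fid), fid_index(st, fid),
                      st$parent[fid], st$soma[fid], st$shape[fid],
                      st$orig[fid, 1], st$orig[fid, 2], st$orig[fid, 3],
                      st$end[fid, 1], st$end[fid, 2], st$end[fid, 3],
                      st$radius[fid], st$order[fid], st$path_length[fid],
                      st$status[fid], st$birth_cycle[fid],
                      st$death_cycle[fid], st$swc_type[fid],
                      st$filipodium[fid], st$axon_tip[fid],
                      as.integer(st$has_trailing_axon[fid])))
    }
    # status / soma-bookkeeping updates for fronts touched this cycle
    touched <- unique(c(
      vapply(Filter(function(d) d$cycle == cyc, sim$dispatch_log),
             `[[`, 0L, "fid"), created))
    touched <- sort(touched[touched > 0L & st$used[touched]])
    for (fid in touched) {
      DBI::dbExecute(con, paste(
        "UPDATE fronts SET status = ?, orig_x = ?, orig_y = ?, orig_z = ?,",
        "end_x = ?, end_y = ?, end_z = ?, filipodium = ?, axon_tip = ?,",
        "has_trailing_axon = ? WHERE fid = ?"),
        params = list(st$status[fid], st$orig[fid, 1], st$orig[fid, 2],
                      st$orig[fid, 3], st$end[fid, 1], st$end[fid, 2],
                      st$end[fid, 3], st$filipodium[fid], st$axon_tip[fid],
                      as.integer(st$has_trailing_axon[fid]), fid))
    }
    for (fid in sort(retracted)) {
      DBI::dbExecute(con,
        "UPDATE fronts SET death_cycle = ?, status = 0 WHERE fid = ?",
        params = list(cyc, fid))
    }
    for (i in unique(sim$pend_mig)) {
      DBI::dbExecute(con, "INSERT INTO migration_history VALUES (?,?,?,?,?)",
                     params = unname(as.list(sim$migration_history[i, ])))
    }
    for (i in sort(unique(sim$pend_syn))) {
      DBI::dbExecute(con, "INSERT OR REPLACE INTO synapses VALUES (?,?,?,?,?,?)",
        params = list(i, sim$synapses$pre[i], sim$synapses$post[i],
                      sim$synapses$weight[i], sim$synapses$birth_cycle[i],
                      sim$synapses$death_cycle[i]))
    }
    for (i in sort(unique(sim$pend_sub))) {
      DBI::dbExecute(con, "INSERT OR REPLACE INTO substrate VALUES (?,?,?,?,?,?,?,?)",
        params = c(list(i), unname(as.list(sim$substrate[i, ]))))
    }
    DBI::dbExecute(con, "INSERT OR REPLACE INTO meta VALUES ('cycle', ?)",
                   params = list(as.character(cyc)))
    DBI::dbExecute(con, "COMMIT")
    TRUE
  }, error = function(e) {
    try(DBI::dbExecute(con, "ROLLBACK"), silent = TRUE)
    stop(e)
  })
  sim$pend_fronts <- integer(0); sim$pend_neurons <- integer(0)
  sim$pend_mig <- integer(0); sim$pend_syn <- integer(0)
  sim$pend_sub <- integer(0)
  invisible(ok)
}

#' Read a simulation trace database
#'
#' Loads all tables of a trace database into data frames, without touching
#' any simulation state. [import_simulation()] uses this to resume a run.
#'
#' @param path path to a trace database file.
#' @return a list of data frames: `meta`, `neuron_types`, `neurons`,
#'   `fronts`, `migration_history`, `synapses`, `substrate`.
#' @export
read_simulation <- function(path) {
  if (!file.exists(path)) usage_error(sprintf("no such database: %s", path))
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con))
  tabs <- c("meta", "neuron_types", "neurons", "fronts",
            "migration_history", "synapses", "substrate")
  have <- DBI::dbListTables(con)
  if (!all(tabs %in% have)) {
    usage_error("not a simulation trace database (missing tables)")
  }
  out <- lapply(tabs, function(t) DBI::dbReadTable(con, t))
  names(out) <- tabs
  ver <- out$meta$value[out$meta$key == "schema_version"]
  if (!length(ver) || as.integer(ver) != SCHEMA_VERSION) {
    usage_error("trace database schema version mismatch")
  }
  out
}

#' Resume from a previous simulation database
#'
#' Restores fronts, the neuron registry, synapses, substrate, migration
#' history and the cycle counter into a freshly created simulation, which
#' must have been constructed with the same neuron type list (names and
#' order) and compatible capacities. Continuing the run appends to the new
#' simulation's own database. In serial mode a resumed run reproduces the
#' remainder of an uninterrupted run with the same seed, because every
#' cycle's RNG streams are derived from (seed, core, cycle).
#'
#' @param sim a freshly constructed simulation (no fronts yet).
#' @param path path to the trace database to import.
#' @return the simulation object, invisibly.
#' @export
import_simulation <- function(sim, path) {
  if (any(sim$store$used)) {
    usage_error("import_simulation must be called on a fresh simulation")
  }
  trace <- read_simulation(path)
  if (!identical(trace$neuron_types$name[order(trace$neuron_types$row)],
                 names(sim$types))) {
    usage_error("neuron type registry does not match the database")
  }
  meta <- stats::setNames(trace$meta$value, trace$meta$key)
  if (as.integer(meta[["section_size"]]) != sim$store$section_size) {
    usage_error("section_size does not match the database")
  }
  st <- sim$store
  fr <- trace$fronts[order(trace$fronts$birth_cycle, trace$fronts$fid), , drop = FALSE]
  for (i in seq_len(nrow(fr))) {
    f <- fr[i, ]
    fid <- f$fid
    st$used[fid] <- TRUE
    st$shape[fid] <- f$shape
    st$orig[fid, ] <- c(f$orig_x, f$orig_y, f$orig_z)
    st$end[fid, ] <- c(f$end_x, f$end_y, f$end_z)
    st$radius[fid] <- f$radius
    st$birth_cycle[fid] <- f$birth_cycle
    st$death_cycle[fid] <- if (is.na(f$death_cycle)) NA_integer_ else f$death_cycle
    st$swc_type[fid] <- f$swc_type
    st$status[fid] <- f$status
    st$filipodium[fid] <- f$filipodium
    st$axon_tip[fid] <- f$axon_tip
    st$has_filipodium[fid] <- f$filipodium != 0L
    st$has_trailing_axon[fid] <- f$has_trailing_axon != 0L
    if (f$shape == SHAPE_SPHERE) {
      st$order[fid] <- 0L
      st$path_length[fid] <- 0
      st$soma[fid] <- fid
    }
    if (!is.na(f$death_cycle)) {
      st$retracted[fid] <- TRUE
      st$status[fid] <- STATUS_DISABLED
      st$parent[fid] <- f$parent
      st$soma[fid] <- f$soma
    }
  }
  # rebuild tree links for live fronts in creation order
  for (i in seq_len(nrow(fr))) {
    f <- fr[i, ]
    if (!is.na(f$death_cycle) || f$shape == SHAPE_SPHERE) next
    st$parent[f$fid] <- f$parent
    attach_child_restore(st, f$parent, f$fid)
  }
  # restore section counters from the highest used index per section
  for (r in seq_len(st$n_rows)) {
    for (s in seq_len(st$n_sections)) {
      lo <- (r - 1L) * st$capacity + (s - 1L) * st$section_size
      offs <- which(st$used[(lo + 1L):(lo + st$section_size)])
      st$counters[r, s] <- if (length(offs)) max(offs) + 1L else 1L
    }
  }
  # register live fronts on the grid (owner = the section that created them)
  for (fid in sort(live_fids(st))) {
    ax <- front_axis(st, fid)
    gids <- front_to_gids(sim$grid_config, ax$p0, ax$p1)
    pid <- (fid_index(st, fid) - 1L) %/% st$section_size + 1L
    for (g in gids) grid_register(sim$grid, pid, g, fid)
    sim$fid_gids[[as.character(fid)]] <- gids
  }
  sim$neurons <- trace$neurons
  sim$firing_rate <- rep(0, nrow(trace$neurons))
  if (nrow(trace$synapses)) {
    sim$synapses <- trace$synapses[order(trace$synapses$id),
                                   c("pre", "post", "weight", "birth_cycle",
                                     "death_cycle")]
    rownames(sim$synapses) <- NULL
  }
  if (nrow(trace$substrate)) {
    sim$substrate <- trace$substrate[order(trace$substrate$id),
                                     c("name", "x", "y", "z", "n_mol", "D",
                                       "birth_cycle")]
    rownames(sim$substrate) <- NULL
  }
  sim$migration_history <- trace$migration_history
  sim$cycle <- as.integer(meta[["cycle"]])
  if (!is.null(sim$db)) {
    # seed the new database with the full imported history
    sim$pend_fronts <- which(st$used)
    sim$pend_neurons <- seq_len(nrow(sim$neurons))
    sim$pend_mig <- seq_len(nrow(sim$migration_history))
    sim$pend_syn <- seq_len(nrow(sim$synapses))
    sim$pend_sub <- seq_len(nrow(sim$substrate))
    persist_cycle(sim)
  }
  invisible(sim)
}

# re-link a restored child without recomputing path_length/order from scratch
# (attach_child recomputes both consistently, so reuse it)
attach_child_restore <- function(store, parent, child) {
  store$parent[child] <- 0L
  attach_child(store, parent, child)
}

# SWC export --------------------------------------------------------------------

#' Export a neuron's morphology as an SWC file
#'
#' Writes the standard 7-column SWC representation of one neuron: sample 1
#' is the soma (type 1) at its centre, every live cylindrical front
#' contributes one sample at its distal (`end`) coordinate with a parent
#' link, in depth-first order over the (creation-ordered) child lists.
#' Retracted fronts are excluded.
#'
#' @param sim a simulation object, or the path of a trace database.
#' @param neuron neuron name as recorded by [add_neurons()].
#' @param file output path.
#' @return the output path, invisibly.
#' @export
export_swc <- function(sim, neuron, file) {
  if (is.character(sim)) {
    trace <- read_simulation(sim)
    idx <- match(neuron, trace$neurons$name)
    if (is.na(idx)) usage_error(sprintf("unknown neuron '%s'", neuron))
    soma <- trace$neurons$soma[idx]
    fr <- trace$fronts[is.na(trace$fronts$death_cycle), , drop = FALSE]
    kids <- split(fr$fid, fr$parent)
    get_children <- function(f) sort(kids[[as.character(f)]])
    rec <- function(f) {
      i <- match(f, fr$fid)
      list(shape = fr$shape[i], orig = c(fr$orig_x[i], fr$orig_y[i], fr$orig_z[i]),
           end = c(fr$end_x[i], fr$end_y[i], fr$end_z[i]),
           radius = fr$radius[i], swc_type = fr$swc_type[i])
    }
  } else {
    idx <- match(neuron, sim$neurons$name)
    if (is.na(idx)) usage_error(sprintf("unknown neuron '%s'", neuron))
    soma <- sim$neurons$soma[idx]
    st <- sim$store
    get_children <- function(f) children_of(st, f)
    rec <- function(f) {
      list(shape = st$shape[f], orig = st$orig[f, ], end = st$end[f, ],
           radius = st$radius[f], swc_type = st$swc_type[f])
    }
  }
  lines <- c("# SWC export", sprintf("# neuron: %s", neuron),
             "# id type x y z radius parent")
  sample_of <- new.env(parent = emptyenv())
  n <- 0L
  emit <- function(f, parent_sample) {
    n <<- n + 1L
    r <- rec(f)
    p <- if (r$shape == SHAPE_SPHERE) r$orig else r$end
    ty <- if (r$shape == SHAPE_SPHERE) 1L else r$swc_type
    lines <<- c(lines, sprintf("%d %d %.6f %.6f %.6f %.6f %d",
                               n, ty, p[1], p[2], p[3], r$radius, parent_sample))
    my <- n
    for (ch in get_children(f)) emit(ch, my)
  }
  emit(soma, -1L)
  writeLines(lines, file)
  invisible(file)
}
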