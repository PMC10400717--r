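# Fixed-capacity front store ------------------------------------------------
#
# All fronts live in preallocated parallel arrays, mirroring a shared-memory
# layout: one logical "row" per front subclass, each row subdivided into
# num_procs + 1 equal private sections (section 1 belongs to the admin, which
# only ever creates somata; sections 2..N+1 to the workers). A core only ever
# writes fronts into its own section, so allocation is conflict-free by
# construction. Index 0 means "empty" everywhere; all ids are numbered from 1.
#
# A front id is the pair (row, index); internally it is encoded as the single
# integer (row - 1) * capacity + index so ids can live in plain integer
# vectors (registries, grid blocks, instruction slots).

STATUS_DISABLED  <- 0L
STATUS_GROWING   <- 1L
STATUS_MIGRATING <- 2L
STATUS_ACTIVE    <- 3L

SHAPE_SPHERE   <- 1L
SHAPE_CYLINDER <- 2L

new_front_store <- function(n_rows, n_sections, section_size) {
  stopifnot(n_rows >= 1, n_sections >= 1, section_size >= 1)
  capacity <- n_sections * section_size
  n <- n_rows * capacity
  st <- new.env(parent = emptyenv())
  st$n_rows <- as.integer(n_rows)
  st$n_sections <- as.integer(n_sections)
  st$section_size <- as.integer(section_size)
  st$capacity <- as.integer(capacity)

  st$used <- logical(n)
  st$shape <- integer(n)
  st$orig <- matrix(NA_real_, n, 3L)
  st$end <- matrix(NA_real_, n, 3L)
  st$radius <- numeric(n)
  st$order <- integer(n)
  st$path_length <- numeric(n)
  st$parent <- integer(n)
  st$first_child <- integer(n)
  st$next_sibling <- integer(n)
  st$soma <- integer(n)
  st$num_children <- integer(n)
  st$status <- integer(n)
  st$retracted <- logical(n)
  st$has_filipodium <- logical(n)
  st$has_trailing_axon <- logical(n)
  st$filipodium <- integer(n)   # soma only: fid of its filipodium child
  st$axon_tip <- integer(n)     # soma only: fid of the distal trailing-axon front
  st$birth_cycle <- integer(n)
  st$death_cycle <- integer(n)
  st$swc_type <- integer(n)
  # next free offset (1-based within section) per (row, section)
  st$counters <- matrix(1L, n_rows, n_sections)
  st
}

fid_encode <- function(store, row, index) {
  (as.integer(row) - 1L) * store$capacity + as.integer(index)
}

fid_row <- function(store, fid) ((fid - 1L) %/% store$capacity) + 1L
fid_index <- function(store, fid) ((fid - 1L) %% store$capacity) + 1L

format_fid <- function(fid) {
  if (is.list(fid)) sprintf("(%d,%d)", fid$row, fid$index) else sprintf("#%d", fid)
}

#' Decode a front id into its (row, index) pair
#'
#' Fronts are addressed by a pair: the subclass row they belong to and their
#' index within that row's fixed-size array. Index 0 is reserved to mean
#' empty. This helper exposes the pair form of the opaque integer ids
#' returned by the engine.
#'
#' @param sim a simulation object.
#' @param fid an integer front id as returned by e.g. [add_child()].
#' @return a list with elements `row` and `index`.
#' @export
front_id_pair <- function(sim, fid) {
  st <- sim$store
  list(row = fid_row(st, fid), index = fid_index(st, fid))
}

# Allocate the next free slot of `row` in the private section of core `pid`.
# Signals overflowError naming the subclass array when the section is full.
store_allocate <- function(store, pid, row, row_name = NULL) {
  stopifnot(pid >= 1, pid <= store$n_sections, row >= 1, row <= store$n_rows)
  offset <- store$counters[row, pid]
  if (offset > store$section_size) {
    overflow_error(if (is.null(row_name)) sprintf("fronts[row %d]", row) else
      sprintf("fronts[%s]", row_name))
  }
  store$counters[row, pid] <- offset + 1L
  index <- (pid - 1L) * store$section_size + offset
  fid_encode(store, row, index)
}

store_rollback <- function(store, pid, row) {
  store$counters[row, pid] <- store$counters[row, pid] - 1L
}

live_fids <- function(store) {
  which(store$used & !store$retracted)
}

# Child geometry -------------------------------------------------------------

# Given a parent front, a desired end position and radius, derive the child's
# (orig, end). A cylinder child of a cylinder starts at the parent's end; a
# child of a soma starts on the soma surface along the ray from the centre to
# new_pos, so a position 15 um from the centre of a 10 um soma yields a 5 um
# root. new_pos strictly inside the parent signals insideParentError.
make_child_geometry_raw <- function(parent_shape, parent_orig, parent_end,
                                    parent_radius, new_pos) {
  if (parent_shape == SHAPE_SPHERE) {
    d <- new_pos - parent_orig
    len <- norm3(d)
    if (len <= parent_radius + 1e-12) {
      inside_parent_error()
    }
    orig <- parent_orig + d / len * parent_radius
  } else {
    dist <- point_seg_dist_many(new_pos,
                                matrix(parent_orig, 1L, 3L, byrow = TRUE),
                                matrix(parent_end, 1L, 3L, byrow = TRUE))[1L]
    if (dist < parent_radius - 1e-12) {
      inside_parent_error()
    }
    orig <- parent_end
  }
  list(orig = orig, end = new_pos)
}

#' Derive a child's cylinder geometry from its parent
#'
#' Children of cylinders start at the parent's `end` coordinate; children of
#' somata start on the soma surface along the ray from the soma centre to
#' `new_pos`. Only the distal coordinate of a new front needs to be chosen by
#' a growth rule; the proximal one is implied by the parent.
#'
#' @param sim a simulation object.
#' @param parent front id of the parent.
#' @param new_pos numeric length-3 target end coordinate (um).
#' @return a list with `orig` and `end` coordinates.
#' @export
make_child_geometry <- function(sim, parent, new_pos) {
  st <- sim$store
  make_child_geometry_raw(st$shape[parent], st$orig[parent, ], st$end[parent, ],
                          st$radius[parent], new_pos)
}

# Tree linkage ----------------------------------------------------------------

# Append child to parent's intrusive child list (creation order preserved),
# set order / soma / path_length. For a soma parent the path length is the
# distance from the child's end to the soma centre, i.e. radius + |end-orig|.
attach_child <- function(store, parent, child) {
  store$parent[child] <- parent
  if (store$first_child[parent] == 0L) {
    store$first_child[parent] <- child
  } else {
    f <- store$first_child[parent]
    while (store$next_sibling[f] != 0L) f <- store$next_sibling[f]
    store$next_sibling[f] <- child
  }
  store$num_children[parent] <- store$num_children[parent] + 1L
  store$order[child] <- store$order[parent] + 1L
  seg <- norm3(store$end[child, ] - store$orig[child, ])
  if (store$shape[parent] == SHAPE_SPHERE) {
    store$soma[child] <- parent
    store$path_length[child] <- store$radius[parent] + seg
  } else {
    store$soma[child] <- store$soma[parent]
    store$path_length[child] <- store$path_length[parent] + seg
  }
  invisible(child)
}

children_of <- function(store, fid) {
  out <- integer(0)
  f <- store$first_child[fid]
  while (f != 0L) {
    out <- c(out, f)
    f <- store$next_sibling[f]
  }
  out
}

# Depth-first: the front plus all its descendants.
collect_branch <- function(store, fid) {
  out <- integer(0)
  stack <- fid
  while (length(stack)) {
    f <- stack[[1L]]
    stack <- stack[-1L]
    out <- c(out, f)
    stack <- c(children_of(store, f), stack)
  }
  out
}

unlink_child <- function(store, child) {
  parent <- store$parent[child]
  if (parent == 0L) return(invisible(NULL))
  f <- store$first_child[parent]
  if (f == child) {
    store$first_child[parent] <- store$next_sibling[child]
  } else {
    while (f != 0L && store$next_sibling[f] != child) f <- store$next_sibling[f]
    if (f != 0L) store$next_sibling[f] <- store$next_sibling[child]
  }
  store$next_sibling[child] <- 0L
  store$num_children[parent] <- store$num_children[parent] - 1L
  invisible(NULL)
}

# Flag a front as retracted and unlink it from its parent. Fronts are never
# physically deleted from the store; grid deregistration is the engine's job.
mark_retracted <- function(store, fid, cycle) {
  if (store$retracted[fid]) {
    usage_error(sprintf("front %d is already retracted", fid))
  }
  store$retracted[fid] <- TRUE
  store$status[fid] <- STATUS_DISABLED
  store$death_cycle[fid] <- as.integer(cycle)
  unlink_child(store, fid)
  invisible(NULL)
}

# Status --------------------------------------------------------------------

#' Enable or disable a front for scheduling
#'
#' Disabled fronts are never dispatched again until re-enabled. A growth rule
#' typically disables `self` once its job is done (e.g. a soma after its
#' dendritic roots exist, or a tip whose path length reached the termination
#' bound). `status` picks the scheduling category used by the cycle loop:
#' growing fronts are dispatched first, then migrating, then other active
#' fronts.
#'
#' @param sim a simulation object.
#' @param fid front id.
#' @param status one of `"growing"`, `"migrating"`, `"active"`.
#' @return the front id, invisibly.
#' @export
enable_front <- function(sim, fid, status = c("growing", "migrating", "active")) {
  status <- match.arg(status)
  sim$store$status[fid] <- switch(status,
    growing = STATUS_GROWING, migrating = STATUS_MIGRATING, active = STATUS_ACTIVE)
  invisible(fid)
}

#' @rdname enable_front
#' @export
disable_front <- function(sim, fid) {
  sim$store$status[fid] <- STATUS_DISABLED
  invisible(fid)
}

#' Inspect a front
#'
#' Returns a snapshot of one front's record: identity, geometry, tree links,
#' status and bookkeeping.
#'
#' @param sim a simulation object.
#' @param fid front id.
#' @return a list of front fields.
#' @export
front_info <- function(sim, fid) {
  st <- sim$store
  stopifnot(fid >= 1, fid <= length(st$used), st$used[fid])
  list(
    fid = fid,
    id = list(row = fid_row(st, fid), index = fid_index(st, fid)),
    shape = if (st$shape[fid] == SHAPE_SPHERE) "sphere" else "cylinder",
    orig = st$orig[fid, ],
    end = st$end[fid, ],
    radius = st$radius[fid],
    order = st$order[fid],
    path_length = st$path_length[fid],
    parent = st$parent[fid],
    children = children_of(st, fid),
    num_children = st$num_children[fid],
    soma = st$soma[fid],
    status = c("disabled", "growing", "migrating", "active")[st$status[fid] + 1L],
    retracted = st$retracted[fid],
    has_filipodium = st$has_filipodium[fid],
    has_trailing_axon = st$has_trailing_axon[fid],
    birth_cycle = st$birth_cycle[fid],
    death_cycle = st$death_cycle[fid],
    swc_type = st$swc_type[fid]
  )
}

# The capsule axis of a front: spheres are degenerate segments (orig, orig).
front_axis <- function(store, fid) {
  if (store$shape[fid] == SHAPE_SPHERE) {
    list(p0 = store$orig[fid, ], p1 = store$orig[fid, ])
  } else {
    list(p0 = store$orig[fid, ], p1 = store$end[fid, ])
  }
}

# Structural adjacency: parent/child pairs; siblings sharing the same origin
# anchor (branch children all start at their parent's end point, so their
# axis distance is 0 by construction and must not count as a collision --
# soma roots have distinct surface origins and ARE checked); and a migrating
# soma against its own trailing-axon chain, which is deposited in the space
# the soma just vacated and legitimately hugs it on curved paths.
structurally_adjacent <- function(store, a, b) {
  if (store$parent[a] == b || store$parent[b] == a) return(TRUE)
  if (store$parent[a] != 0L && store$parent[a] == store$parent[b]) {
    if (sum((store$orig[a, ] - store$orig[b, ])^2) < 1e-18) return(TRUE)
  }
  if (store$shape[a] == SHAPE_SPHERE && store$soma[b] == a &&
      store$swc_type[b] == 2L && store$has_trailing_axon[a]) return(TRUE)
  if (store$shape[b] == SHAPE_SPHERE && store$soma[a] == b &&
      store$swc_type[a] == 2L && store$has_trailing_axon[b]) return(TRUE)
  FALSE
}
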