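# Uniform collision grid ------------------------------------------------------
#
# A lattice with spacing grid_step spans the simulation volume. Every front is
# registered at one or more lattice points (gids); a collision query for a
# candidate capsule only tests fronts registered at the candidate's gids and
# their 26 neighbours. Registered ids are kept in linked blocks inside a
# single preallocated grid_extra array that is subdivided into per-core
# private sections: a core allocates new blocks only in its own section, but
# once a block exists any core may write entries into it (under the grid
# locks). The last slot of a full block holds a link to its continuation
# block, stored as a negative index.

new_grid_config <- function(volume_min, volume_max, grid_step = 20,
                            block_size = 10L) {
  stopifnot(grid_step > 0, all(volume_max > volume_min))
  dims <- pmax(2L, as.integer(floor((volume_max - volume_min) / grid_step)) + 1L)
  list(
    grid_step = grid_step,
    volume_min = volume_min,
    volume_max = volume_max,
    block_size = as.integer(block_size),
    nx = dims[1L], ny = dims[2L], nz = dims[3L],
    n_gids = dims[1L] * dims[2L] * dims[3L]
  )
}

new_grid_map <- function(config, n_sections, section_blocks = 512L) {
  gm <- new.env(parent = emptyenv())
  gm$config <- config
  gm$n_sections <- as.integer(n_sections)
  gm$section_blocks <- as.integer(section_blocks)
  gm$block_size <- config$block_size
  gm$grid <- integer(config$n_gids)            # 0 or index of first block
  gm$extra <- integer(n_sections * section_blocks * config$block_size)
  gm$block_counter <- rep(1L, n_sections)      # next free block per section
  gm$free_blocks <- vector("list", n_sections) # recycled block starts
  gm
}

# gid = 1 + ix + nx * (iy + ny * iz), 0-based lattice coordinates.
.cell_corners <- as.matrix(expand.grid(0:1, 0:1, 0:1))
.chebyshev_offsets <- local({
  m <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  m[rowSums(abs(m)) > 0, , drop = FALSE]
})

lattice_to_gid <- function(config, ix, iy, iz) {
  1L + ix + config$nx * (iy + config$ny * iz)
}

gid_to_lattice <- function(config, gid) {
  g <- gid - 1L
  ix <- g %% config$nx
  g <- g %/% config$nx
  cbind(ix = ix, iy = g %% config$ny, iz = g %/% config$ny)
}

lattice_point <- function(config, ixyz) {
  matrix(config$volume_min, nrow(ixyz), 3L, byrow = TRUE) +
    ixyz * config$grid_step
}

in_volume <- function(config, p) {
  all(p >= config$volume_min - 1e-9) && all(p <= config$volume_max + 1e-9)
}

#' Lattice points a front is allocated to
#'
#' Maps a capsule (or sphere, as a degenerate capsule) to the set of grid
#' points that index it for collision detection. The axis is sampled at most
#' half a grid step apart (endpoints included); each sample contributes its
#' nearest lattice point, plus any lattice point whose distance to the sample
#' is within a quarter grid step of the nearest (the "about equally close"
#' rule). Every front gets at least one gid, and the rule guarantees that two
#' colliding fronts of radius below half the grid step always map to gid sets
#' within one Chebyshev step of each other, which makes the grid-restricted
#' collision query equivalent to a brute-force all-pairs test.
#'
#' @param config a grid configuration.
#' @param p0,p1 capsule axis endpoints (um); equal for spheres.
#' @return sorted integer vector of gids.
#' @keywords internal
front_to_gids <- function(config, p0, p1) {
  if (!in_volume(config, p0) || !in_volume(config, p1)) {
    volume_error("front geometry outside the simulation volume")
  }
  step <- config$grid_step
  len <- norm3(p1 - p0)
  n_samp <- max(2L, as.integer(ceiling(len / (step / 2))) + 1L)
  t <- seq(0, 1, length.out = n_samp)
  S <- outer(1 - t, p0) + outer(t, p1)         # n x 3 sample points
  rel <- (S - matrix(config$volume_min, n_samp, 3L, byrow = TRUE)) / step
  dims <- c(config$nx, config$ny, config$nz)
  gids <- integer(0)
  for (i in seq_len(n_samp)) {
    base <- floor(rel[i, ])
    ixyz <- sweep(.cell_corners, 2L, base, "+")
    ixyz <- pmax(ixyz, 0L)
    ixyz <- sweep(ixyz, 2L, dims - 1L, pmin)
    ixyz <- unique(ixyz)
    d <- sqrt(rowSums((sweep(ixyz, 2L, rel[i, ], "-") * step)^2))
    keep <- d <= min(d) + 0.25 * step + 1e-9
    gids <- c(gids, lattice_to_gid(config, ixyz[keep, 1L], ixyz[keep, 2L],
                                   ixyz[keep, 3L]))
  }
  sort(unique(as.integer(gids)))
}

#' Neighbouring grid points
#'
#' All lattice points at Chebyshev distance one from `gid` (26 in the
#' interior), clipped at the volume borders.
#'
#' @param config a grid configuration.
#' @param gid a grid point index.
#' @return integer vector of neighbouring gids (excluding `gid`).
#' @keywords internal
grid_neighbors <- function(config, gid) {
  l <- gid_to_lattice(config, gid)
  off <- .chebyshev_offsets
  ix <- l[1L] + off[, 1L]; iy <- l[2L] + off[, 2L]; iz <- l[3L] + off[, 3L]
  ok <- ix >= 0 & ix < config$nx & iy >= 0 & iy < config$ny &
    iz >= 0 & iz < config$nz
  as.integer(lattice_to_gid(config, ix[ok], iy[ok], iz[ok]))
}

# Block management ------------------------------------------------------------

grid_alloc_block <- function(gm, pid) {
  fl <- gm$free_blocks[[pid]]
  if (length(fl)) {
    start <- fl[[1L]]
    gm$free_blocks[[pid]] <- fl[-1L]
    return(start)
  }
  b <- gm$block_counter[pid]
  if (b > gm$section_blocks) overflow_error("grid_extra")
  gm$block_counter[pid] <- b + 1L
  (pid - 1L) * gm$section_blocks * gm$block_size + (b - 1L) * gm$block_size + 1L
}

grid_free_block <- function(gm, start) {
  # return a block to the free list of the section that owns it
  pid <- (start - 1L) %/% (gm$section_blocks * gm$block_size) + 1L
  gm$extra[start:(start + gm$block_size - 1L)] <- 0L
  gm$free_blocks[[pid]] <- c(gm$free_blocks[[pid]], start)
}

# Walk the block chain of a gid, returning c(entries, slots) where slots are
# the extra-array positions holding each entry (link slots skipped).
grid_chain <- function(gm, gid) {
  entries <- integer(0); slots <- integer(0)
  b <- gm$grid[gid]
  bs <- gm$block_size
  while (b != 0L) {
    vals <- gm$extra[b:(b + bs - 1L)]
    link <- 0L
    if (vals[bs] < 0L) {
      link <- -vals[bs]
      vals <- vals[-bs]
      idx <- b:(b + bs - 2L)
    } else {
      idx <- b:(b + bs - 1L)
    }
    keep <- vals != 0L
    entries <- c(entries, vals[keep])
    slots <- c(slots, idx[keep])
    b <- link
  }
  list(entries = entries, slots = slots)
}

# Register front_id at gid. Blocks fill front to back; when the last slot of
# a full block is needed, a new block is allocated, the id residing in the
# last slot moves to the new block's first slot, the last slot becomes the
# link, and the new id lands in the new block's second slot.
grid_register <- function(gm, pid, gid, front_id) {
  bs <- gm$block_size
  if (gm$grid[gid] == 0L) {
    start <- grid_alloc_block(gm, pid)
    gm$grid[gid] <- start
    gm$extra[start] <- front_id
    return(invisible(NULL))
  }
  b <- gm$grid[gid]
  repeat {
    vals <- gm$extra[b:(b + bs - 1L)]
    if (vals[bs] < 0L) {
      free <- which(vals[-bs] == 0L)
      if (length(free)) {
        gm$extra[b + free[1L] - 1L] <- front_id
        return(invisible(NULL))
      }
      b <- -vals[bs]
    } else {
      free <- which(vals == 0L)
      if (length(free)) {
        gm$extra[b + free[1L] - 1L] <- front_id
        return(invisible(NULL))
      }
      # block completely full: chain a continuation block
      new_start <- grid_alloc_block(gm, pid)
      moved <- gm$extra[b + bs - 1L]
      gm$extra[new_start] <- moved
      gm$extra[new_start + 1L] <- front_id
      gm$extra[b + bs - 1L] <- -new_start
      return(invisible(NULL))
    }
  }
}

# Deregister front_id at gid: the removed entry is replaced by the last
# entry of the chain. Empty chains release their blocks and reset the gid.
grid_deregister <- function(gm, gid, front_id) {
  ch <- grid_chain(gm, gid)
  pos <- match(front_id, ch$entries)
  if (is.na(pos)) {
    usage_error(sprintf("front %d is not registered at gid %d", front_id, gid))
  }
  last <- length(ch$entries)
  gm$extra[ch$slots[pos]] <- ch$entries[last]
  gm$extra[ch$slots[last]] <- 0L
  if (last == 1L) {
    # chain now empty: free all blocks of this gid
    b <- gm$grid[gid]
    bs <- gm$block_size
    while (b != 0L) {
      nxt <- if (gm$extra[b + bs - 1L] < 0L) -gm$extra[b + bs - 1L] else 0L
      grid_free_block(gm, b)
      b <- nxt
    }
    gm$grid[gid] <- 0L
  } else {
    # drop a trailing continuation block if it became empty
    repeat {
      b <- gm$grid[gid]; prev <- 0L
      bs <- gm$block_size
      while (gm$extra[b + bs - 1L] < 0L) {
        prev <- b
        b <- -gm$extra[b + bs - 1L]
      }
      if (prev != 0L && all(gm$extra[b:(b + bs - 1L)] == 0L)) {
        # restore the link slot of prev to a plain (empty) slot
        gm$extra[prev + bs - 1L] <- 0L
        grid_free_block(gm, b)
      } else break
    }
  }
  invisible(NULL)
}

# Collision query --------------------------------------------------------------

# Ids registered on G union neighbours(G), deduplicated in deterministic scan
# order (ascending gid, then block order).
grid_candidates <- function(gm, gids) {
  all_gids <- sort(unique(c(gids, unlist(lapply(gids, grid_neighbors,
                                                config = gm$config)))))
  out <- integer(0)
  for (g in all_gids) {
    if (gm$grid[g] != 0L) out <- c(out, grid_chain(gm, g)$entries)
  }
  out[!duplicated(out)]
}

# Test a candidate capsule against registered live fronts. Collision is
# strict: axis distance < sum of radii (touching is not a collision).
# `exclude` drops structural contacts (self, parent, same-origin siblings).
grid_collision_query <- function(gm, store, p0, p1, radius, gids,
                                 exclude = integer(0), mode = c("first", "all")) {
  mode <- match.arg(mode)
  cand <- grid_candidates(gm, gids)
  cand <- cand[store$used[cand] & !store$retracted[cand]]
  if (length(exclude)) cand <- setdiff(cand, exclude)
  if (!length(cand)) {
    return(if (mode == "first") 0L else integer(0))
  }
  Q0 <- store$orig[cand, , drop = FALSE]
  Q1 <- store$end[cand, , drop = FALSE]
  sph <- store$shape[cand] == SHAPE_SPHERE
  Q1[sph, ] <- Q0[sph, , drop = FALSE]
  d <- seg_dist_many(p0, p1, Q0, Q1)
  hit <- d < radius + store$radius[cand] - 1e-12
  if (mode == "first") {
    if (any(hit)) cand[which(hit)[1L]] else 0L
  } else {
    cand[hit]
  }
}

#' Grid occupancy statistics
#'
#' Computes the occupancy metrics used to judge whether `grid_step` matches
#' the front sizes of a model: the mean number of grid points each live
#' front is registered at, the fraction of all grid points that are
#' occupied, the fractions of occupied points holding 1--5 and 1--10 fronts,
#' and the largest number of fronts at any single grid point.
#'
#' @param sim a simulation object.
#' @return a one-row `data.frame` with columns `mean_gids_per_front`,
#'   `occupancy`, `frac_1_5`, `frac_1_10`, `max_fronts_per_gid`,
#'   `live_fronts`, `occupied_gids`.
#' @export
grid_stats <- function(sim) {
  gm <- sim$grid
  occupied <- which(gm$grid != 0L)
  counts <- integer(length(occupied))
  per_front <- integer(0)
  for (i in seq_along(occupied)) {
    e <- grid_chain(gm, occupied[i])$entries
    counts[i] <- length(e)
    per_front <- c(per_front, e)
  }
  n_live <- length(live_fids(sim$store))
  tab <- table(per_front)
  data.frame(
    mean_gids_per_front = if (n_live) length(per_front) / n_live else NA_real_,
    occupancy = length(occupied) / gm$config$n_gids,
    frac_1_5 = if (length(counts)) mean(counts >= 1 & counts <= 5) else NA_real_,
    frac_1_10 = if (length(counts)) mean(counts >= 1 & counts <= 10) else NA_real_,
    max_fronts_per_gid = if (length(counts)) max(counts) else 0L,
    live_fronts = n_live,
    occupied_gids = length(occupied)
  )
}
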