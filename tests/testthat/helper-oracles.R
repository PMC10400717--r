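# Independent oracles and scene builders used across the suite.

# Oracle segment-segment distance: for fixed t, the distance from the point
# q0 + t (q1 - q0) to the segment p0-p1 has a closed form; minimising over t
# is a 1D convex problem, solved by golden-section search bracketed on
# [0, 1]. This shares no code path with the production algorithm.
oracle_seg_dist <- function(p0, p1, q0, q1) {
  point_to_seg <- function(q) {
    v <- p1 - p0
    c2 <- sum(v * v)
    t <- if (c2 > 0) min(max(sum((q - p0) * v) / c2, 0), 1) else 0
    sqrt(sum((q - p0 - t * v)^2))
  }
  f <- function(t) point_to_seg(q0 + t * (q1 - q0))
  gr <- (sqrt(5) - 1) / 2
  a <- 0; b <- 1
  c_ <- b - gr * (b - a); d <- a + gr * (b - a)
  for (i in 1:200) {
    if (f(c_) < f(d)) b <- d else a <- c_
    c_ <- b - gr * (b - a); d <- a + gr * (b - a)
  }
  f((a + b) / 2)
}

# Build a simulation whose store is populated directly with random capsules
# and spheres (no growth rules), each registered on the grid. Radii are kept
# below grid_step / 2 so the allocation rule's soundness guarantee applies.
random_scene <- function(n, half = 50, grid_step = 20, r_range = c(0.5, 2),
                         len_range = c(1, 8), seed = 1) {
  set.seed(seed)
  sim <- new_simulation(rep(-half, 3), rep(half, 3),
                        list(neuron_type("scene", function(sim, self) NULL)),
                        seed = seed, grid_step = grid_step,
                        section_size = max(2L * n, 100L))
  st <- sim$store
  for (i in seq_len(n)) {
    repeat {
      p0 <- runif(3, -half + 10, half - 10)
      if (runif(1) < 0.2) { p1 <- p0 } else {
        d <- runif(3, -1, 1); d <- d / sqrt(sum(d^2))
        p1 <- p0 + d * runif(1, len_range[1], len_range[2])
      }
      if (all(abs(p1) <= half)) break
    }
    fid <- neurogrow:::store_allocate(st, 1L, 1L)
    st$used[fid] <- TRUE
    st$shape[fid] <- if (all(p0 == p1)) 1L else 2L
    st$orig[fid, ] <- p0
    st$end[fid, ] <- p1
    st$radius[fid] <- runif(1, r_range[1], r_range[2])
    gids <- neurogrow:::front_to_gids(sim$grid_config, p0, p1)
    for (g in gids) neurogrow:::grid_register(sim$grid, 1L, g, fid)
    sim$fid_gids[[as.character(fid)]] <- gids
  }
  sim
}

# Brute-force verdict for a candidate capsule against every live front:
# returns the sorted ids of all strictly overlapping fronts.
brute_force_hits <- function(sim, p0, p1, radius, exclude = integer(0)) {
  st <- sim$store
  fids <- setdiff(neurogrow:::live_fids(st), exclude)
  if (!length(fids)) return(integer(0))
  Q0 <- st$orig[fids, , drop = FALSE]
  Q1 <- st$end[fids, , drop = FALSE]
  sph <- st$shape[fids] == 1L
  Q1[sph, ] <- Q0[sph, , drop = FALSE]
  d <- neurogrow:::seg_dist_many(p0, p1, Q0, Q1)
  sort(fids[d < radius + st$radius[fids] - 1e-12])
}

# Brute-force all-pairs overlap sweep over live fronts, skipping
# structurally adjacent pairs. Returns the number of colliding pairs.
no_overlap_sweep <- function(sim) {
  st <- sim$store
  fids <- neurogrow:::live_fids(st)
  n <- length(fids)
  if (n < 2) return(0L)
  Q0 <- st$orig[fids, , drop = FALSE]
  Q1 <- st$end[fids, , drop = FALSE]
  sph <- st$shape[fids] == 1L
  Q1[sph, ] <- Q0[sph, , drop = FALSE]
  bad <- 0L
  for (i in seq_len(n - 1)) {
    js <- (i + 1):n
    d <- neurogrow:::seg_dist_many(Q0[i, ], Q1[i, ],
                                   Q0[js, , drop = FALSE], Q1[js, , drop = FALSE])
    hit <- which(d < st$radius[fids[i]] + st$radius[fids[js]] - 1e-12)
    for (h in hit) {
      j <- js[h]
      if (!neurogrow:::structurally_adjacent(st, fids[i], fids[j])) bad <- bad + 1L
    }
  }
  bad
}

# Fixed-direction deterministic growth type used by scheduling tests: somata
# make `n_soma_children` children, order-1 fronts one child, deeper fronts
# none. Directions are deterministic so runs need no RNG.
scripted_type <- function(name, n_soma_children, extend = TRUE) {
  dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0), c(0, -1, 0))
  neuron_type(name, function(sim, self) {
    st <- sim$store
    if (st$order[self] == 0L) {
      for (k in seq_len(n_soma_children)) {
        add_child(sim, self, st$orig[self, ] + dirs[k, ] * 15, radius = 1)
      }
    } else if (extend && st$order[self] == 1L) {
      d <- st$end[self, ] - st$orig[self, ]
      add_child(sim, self, st$end[self, ] + d / sqrt(sum(d^2)) * 5)
    }
    disable_front(sim, self)
  })
}
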