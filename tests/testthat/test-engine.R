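mk_sim <- function(types = list(scripted_type("t", 4L)), ...) {
  new_simulation(c(-100, -100, -100), c(100, 100, 100), types, seed = 1, ...)
}

test_that("neuron seeding respects placement, volume and overlap rules", {
  sim <- mk_sim()
  s1 <- add_neurons(sim, "t", "a", soma_radius = 10, placement = "explicit",
                    positions = matrix(c(-40, 0, 0), 1, 3))
  expect_equal(sim$store$shape[s1], 1L)
  expect_equal(sim$store$order[s1], 0L)
  # 100 um apart: fine; 15 um apart with radius 10: strict overlap
  s2 <- add_neurons(sim, "t", "b", soma_radius = 10, placement = "explicit",
                    positions = matrix(c(60, 0, 0), 1, 3))
  expect_gt(s2, 0L)
  expect_error(add_neurons(sim, "t", "c", soma_radius = 10,
                           placement = "explicit",
                           positions = matrix(c(-25, 0, 0), 1, 3)),
               class = "collisionError")
  expect_error(add_neurons(sim, "t", "d", soma_radius = 10,
                           placement = "explicit",
                           positions = matrix(c(99, 0, 0), 1, 3)),
               class = "volumeError")
  # the seed drives random placement reproducibly
  sA <- mk_sim(); sB <- mk_sim()
  a <- add_neurons(sA, "t", "n", n = 3, soma_radius = 5)
  b <- add_neurons(sB, "t", "n", n = 3, soma_radius = 5)
  expect_equal(sA$store$orig[a, ], sB$store$orig[b, ])
})

test_that("add_child fails atomically with classed conditions", {
  sim <- mk_sim()
  soma <- add_neurons(sim, "t", "n", soma_radius = 10, placement = "explicit",
                      positions = matrix(0, 1, 3))
  counters_before <- sim$store$counters
  used_before <- sum(sim$store$used)
  expect_error(add_child(sim, soma, c(0, 0, 300), radius = 1),
               class = "volumeError")
  expect_error(add_child(sim, soma, c(2, 0, 0), radius = 1),
               class = "insideParentError")
  expect_equal(sim$store$counters, counters_before)
  expect_equal(sum(sim$store$used), used_before)
  expect_true(all(sim$locks$read_lock == 0L) && all(sim$locks$write_lock == 0L))
  # collisions carry the id of the first colliding front
  obstacle <- add_child(sim, soma, c(0, 0, 15), radius = 2)
  err <- tryCatch(add_child(sim, soma, c(1, 0, 14), radius = 2),
                  collisionError = function(e) e)
  expect_s3_class(err, "collisionError")
  expect_equal(err$colliding, obstacle)
  expect_equal(sum(sim$store$used), used_before + 1L)
})

test_that("front methods enforce the self contract during dispatch", {
  seen <- new.env()
  rogue <- neuron_type("rogue", function(sim, self) {
    st <- sim$store
    other <- setdiff(neurogrow:::live_fids(st), self)[1L]
    seen$err <- tryCatch(add_child(sim, other, st$orig[other, ] + c(0, 0, 15)),
                         notSelfError = function(e) e)
    disable_front(sim, self)
  })
  sim <- mk_sim(list(rogue))
  add_neurons(sim, "rogue", "r", n = 2, soma_radius = 5, placement = "explicit",
              positions = rbind(c(-30, 0, 0), c(30, 0, 0)))
  simulation_loop(sim, 1)
  expect_s3_class(seen$err, "notSelfError")
})

test_that("solve_collision deflects around an obstacle or reports failure", {
  sim <- mk_sim()
  soma <- add_neurons(sim, "t", "n", soma_radius = 5, placement = "explicit",
                      positions = matrix(0, 1, 3))
  tip <- add_child(sim, soma, c(10, 0, 0), radius = 1)
  # a thin obstacle directly on the growth path
  ob <- add_neurons(sim, "t", "o", soma_radius = 2, placement = "explicit",
                    positions = matrix(c(17, 0, 0), 1, 3))
  failed <- c(15, 0, 0)
  expect_gt(brute_force_hits(sim, sim$store$end[tip, ], failed, 1,
                             exclude = tip)[1L], 0L)
  alt <- solve_collision(sim, tip, failed, colliding = ob)
  expect_false(is.null(alt))
  g <- make_child_geometry(sim, tip, alt)
  expect_length(brute_force_hits(sim, g$orig, g$end, 1,
                                 exclude = c(tip, soma)), 0L)
  expect_equal(sqrt(sum((alt - sim$store$end[tip, ])^2)), 5, tolerance = 1e-9)
  # no obstacle: first candidate works
  sim2 <- mk_sim()
  soma2 <- add_neurons(sim2, "t", "n", soma_radius = 5, placement = "explicit",
                       positions = matrix(0, 1, 3))
  tip2 <- add_child(sim2, soma2, c(10, 0, 0), radius = 1)
  expect_false(is.null(solve_collision(sim2, tip2, c(15, 0, 0))))
  # fully enclosed tip: every candidate collides
  sim3 <- mk_sim()
  soma3 <- add_neurons(sim3, "t", "n", soma_radius = 5, placement = "explicit",
                       positions = matrix(0, 1, 3))
  tip3 <- add_child(sim3, soma3, c(10, 0, 0), radius = 1)
  # enclose the tip in a dense shell of (mutually overlapping) obstacle
  # spheres injected directly into the scene
  st3 <- sim3$store
  dirs <- neurogrow:::.chebyshev_offsets
  for (i in seq_len(nrow(dirs))) {
    d <- dirs[i, ] / sqrt(sum(dirs[i, ]^2))
    p <- c(10, 0, 0) + 6 * d
    fid <- neurogrow:::store_allocate(st3, 1L, 1L)
    st3$used[fid] <- TRUE; st3$shape[fid] <- 1L
    st3$orig[fid, ] <- p; st3$end[fid, ] <- p; st3$radius[fid] <- 4
    for (g in neurogrow:::front_to_gids(sim3$grid_config, p, p)) {
      neurogrow:::grid_register(sim3$grid, 1L, g, fid)
    }
  }
  expect_null(solve_collision(sim3, tip3, c(15, 0, 0)))
})

test_that("soma migration moves, trails an axon and re-anchors the filipodium", {
  sim <- mk_sim()
  soma <- add_neurons(sim, "t", "m", soma_radius = 5, placement = "explicit",
                      positions = matrix(0, 1, 3))
  ax <- add_child(sim, soma, c(-7, 0, 0), radius = 0.5, kind = "axon")
  fil <- add_child(sim, soma, c(12, 0, 0), radius = 0.4, kind = "filipodium")
  st <- sim$store
  n_before <- sum(st$used)
  migrate_soma(sim, soma, c(5, 0, 0))
  expect_equal(st$orig[soma, ], c(5, 0, 0))
  # one new trailing-axon front of length 5 spans the displacement
  expect_equal(sum(st$used), n_before + 1L)
  new_ax <- st$axon_tip[soma]
  expect_equal(sqrt(sum((st$end[new_ax, ] - st$orig[new_ax, ])^2)), 5)
  expect_equal(st$parent[new_ax], ax)
  # the filipodium kept its tip and re-anchored on the new surface
  expect_equal(st$end[fil, ], c(12, 0, 0))
  expect_equal(st$orig[fil, ], c(10, 0, 0))
  expect_equal(nrow(sim$migration_history), 1L)
  # dendrites forbid migration
  d <- add_child(sim, soma, c(5, 12, 0), radius = 1)
  expect_error(migrate_soma(sim, soma, c(10, 0, 0)), class = "usageError")
})

test_that("blocked migration leaves the soma unchanged", {
  sim <- mk_sim()
  soma <- add_neurons(sim, "t", "m", soma_radius = 5, placement = "explicit",
                      positions = matrix(0, 1, 3))
  add_neurons(sim, "t", "wall", soma_radius = 5, placement = "explicit",
              positions = matrix(c(12, 0, 0), 1, 3))
  expect_error(migrate_soma(sim, soma, c(4, 0, 0)), class = "collisionError")
  expect_equal(sim$store$orig[soma, ], c(0, 0, 0))
  expect_true(all(sim$locks$write_lock == 0L))
})

test_that("retractions queue during the cycle and apply at its end", {
  watcher <- new.env(); watcher$during <- NA
  ty <- neuron_type("w", function(sim, self) {
    st <- sim$store
    if (st$order[self] == 0L && st$num_children[self] > 0L) {
      root <- neurogrow:::children_of(st, self)[1L]
      retract_branch(sim, self, root)
      # queued, not yet applied: the branch is still live mid-cycle
      watcher$during <- length(neurogrow:::live_fids(st))
    }
    disable_front(sim, self)
  })
  sim <- mk_sim(list(ty))
  soma <- add_neurons(sim, "w", "n", soma_radius = 5, placement = "explicit",
                      positions = matrix(0, 1, 3))
  # build a 7-front subtree by hand (cycle 0)
  root <- add_child(sim, soma, c(10, 0, 0), radius = 1)
  l <- add_child(sim, root, c(15, 3, 0)); r <- add_child(sim, root, c(15, -3, 0))
  for (f in c(l, r)) {
    add_child(sim, f, sim$store$end[f, ] + c(5, 2, 0))
    add_child(sim, f, sim$store$end[f, ] + c(5, -2, 0))
  }
  for (f in setdiff(neurogrow:::live_fids(sim$store), soma)) disable_front(sim, f)
  enable_front(sim, soma, "growing")
  live_before <- length(neurogrow:::live_fids(sim$store))
  simulation_loop(sim, 1)
  expect_equal(watcher$during, live_before)            # not applied mid-cycle
  expect_equal(length(neurogrow:::live_fids(sim$store)), live_before - 7L)
  expect_equal(sim$store$num_children[soma], 0L)
  # conservation: created - retracted = live
  st <- sim$store
  expect_equal(sum(st$used) - sum(st$retracted), length(neurogrow:::live_fids(st)))
})

test_that("single-front retraction requires a terminal front", {
  ty <- neuron_type("q", function(sim, self) {
    st <- sim$store
    if (st$num_children[self] > 0L) {
      expect_error(retract(sim, self), class = "usageError")
    } else if (st$order[self] > 0L) {
      retract(sim, self)
    }
    disable_front(sim, self)
  })
  sim <- mk_sim(list(ty))
  soma <- add_neurons(sim, "q", "n", soma_radius = 5, placement = "explicit",
                      positions = matrix(0, 1, 3))
  root <- add_child(sim, soma, c(10, 0, 0), radius = 1)
  tip <- add_child(sim, root, c(15, 0, 0))
  enable_front(sim, soma, "growing")
  enable_front(sim, root, "growing")
  enable_front(sim, tip, "growing")
  simulation_loop(sim, 1)
  # the tip retracted itself; its parent is terminal again
  expect_true(sim$store$retracted[tip])
  expect_equal(sim$store$num_children[root], 0L)
})

test_that("the cycle counter advances even with nothing to do", {
  sim <- mk_sim()
  simulation_loop(sim, 10)
  expect_equal(sim$cycle, 10L)
  expect_equal(sum(sim$store$used), 0L)
})

test_that("enabled fronts occupy exactly one scheduling category", {
  sim <- run_random_growth(seed = 13, n_cycles = 8)
  st <- sim$store
  enabled <- which(st$used & !st$retracted & st$status != 0L)
  cats <- st$status[enabled]
  expect_true(all(cats %in% 1:3))
  backlog <- neurogrow:::cycle_backlog(sim)
  expect_setequal(backlog, enabled)
  expect_equal(length(backlog), length(unique(backlog)))
})

test_that("serial runs with one seed are identical trajectories", {
  a <- run_random_growth(seed = 17, n_cycles = 12)
  b <- run_random_growth(seed = 17, n_cycles = 12)
  expect_identical(a$store$orig, b$store$orig)
  expect_identical(a$store$end, b$store$end)
  expect_identical(a$store$status, b$store$status)
  c_ <- run_random_growth(seed = 18, n_cycles = 12)
  expect_false(identical(a$store$end, c_$store$end))
})

test_that("grown morphologies never overlap (global sweep)", {
  for (s in c(2, 23)) {
    sim <- run_random_growth(seed = s, n_cycles = 15)
    expect_equal(no_overlap_sweep(sim), 0L)
  }
})
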