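test_that("read locking replays the worked arbitration sequence", {
  ls <- neurogrow:::new_lock_state(n_gids = 20L, n_sections = 5L)
  # cores 2 and 3 both request gid 7; core 4 requests gid 11
  ls$rlock_request[2L] <- 7L
  ls$rlock_request[3L] <- 7L
  ls$rlock_request[4L] <- 11L
  neurogrow:::lock_broker_step(ls)
  expect_equal(ls$read_lock[7L], 2L)          # lower core wins, 3 waits
  expect_equal(ls$read_lock[11L], 4L)
  expect_equal(ls$rlock_request[2L], 0L)      # granted requests cleared
  expect_equal(ls$rlock_request[4L], 0L)
  expect_equal(ls$rlock_request[3L], 7L)      # still pending
  # cores 2 and 4 finish reading and clear their locks
  neurogrow:::lock_release(ls, 2L, 7L, "read")
  neurogrow:::lock_release(ls, 4L, 11L, "read")
  neurogrow:::lock_broker_step(ls)
  expect_equal(ls$read_lock[7L], 3L)          # now core 3 gets its turn
  expect_equal(ls$rlock_request[3L], 0L)
  neurogrow:::lock_release(ls, 3L, 7L, "read")
  expect_true(all(ls$read_lock == 0L))
})

test_that("two-stage write locking replays the worked sequence", {
  ls <- neurogrow:::new_lock_state(n_gids = 20L, n_sections = 5L)
  # cores 2 and 3 both request a preliminary write lock on gid 8
  ls$wlock_request[2L] <- 8L
  ls$wlock_request[3L] <- 8L
  neurogrow:::lock_broker_step(ls)
  expect_equal(ls$write_lock[8L], 2L)         # preliminary for core 2
  expect_equal(ls$wlock_request[3L], 8L)      # core 3 keeps waiting
  # reads are allowed during a preliminary write lock
  ls$rlock_request[4L] <- 8L
  neurogrow:::lock_broker_step(ls)
  expect_equal(ls$read_lock[8L], 4L)
  neurogrow:::lock_release(ls, 4L, 8L, "read")
  # core 2 upgrades with the negative gid; the entry flips to -2
  ls$wlock_request[2L] <- -8L
  neurogrow:::lock_broker_step(ls)
  expect_equal(ls$write_lock[8L], -2L)
  # no reads during a full write lock
  ls$rlock_request[4L] <- 8L
  neurogrow:::lock_broker_step(ls)
  expect_equal(ls$read_lock[8L], 0L)
  expect_equal(ls$rlock_request[4L], 8L)
  # core 2 writes and releases; core 3's pending preliminary is granted
  neurogrow:::lock_release(ls, 2L, 8L, "write")
  neurogrow:::lock_broker_step(ls)
  expect_equal(ls$write_lock[8L], 3L)
  expect_equal(ls$read_lock[8L], 4L)          # the read grant resumes too
})

test_that("re-acquiring a held lock is an idempotent grant", {
  ls <- neurogrow:::new_lock_state(10L, 4L)
  r1 <- neurogrow:::lock_acquire(ls, 2L, 3L, "prelim")
  expect_true(r1$ok); expect_false(r1$owned_before)
  r2 <- neurogrow:::lock_acquire(ls, 2L, 3L, "prelim")
  expect_true(r2$ok); expect_true(r2$owned_before)
  expect_equal(ls$write_lock[3L], 2L)
})

test_that("a contended lock times out with a grid-competition error", {
  ls <- neurogrow:::new_lock_state(10L, 4L)
  neurogrow:::lock_acquire(ls, 2L, 5L, "prelim")
  r <- neurogrow:::lock_acquire(ls, 3L, 5L, "prelim", timeout_steps = 10L)
  expect_false(r$ok)
  expect_equal(ls$wlock_request[3L], 0L)      # withdrawn after timeout
  expect_error(neurogrow:::lock_acquire_set(ls, 3L, 5L, "prelim", 5L),
               class = "gridCompetitionError")
  expect_equal(ls$gce[3L], 1L)
  # uncontended acquisition is granted well within the budget
  r2 <- neurogrow:::lock_acquire(ls, 3L, 6L, "prelim", timeout_steps = 2L)
  expect_true(r2$ok)
})

test_that("a lock stress run holds mutual exclusion and balances its ledger", {
  ls <- neurogrow:::new_lock_state(10L, 9L)    # 8 workers, pids 2..9
  ls$audit <- TRUE
  set.seed(99)
  held <- lapply(1:9, function(i) list(read = integer(0), prelim = integer(0),
                                       full = integer(0)))
  check_tables <- function() {
    for (g in 1:10) {
      readers <- which(vapply(held, function(h) g %in% h$read, TRUE))
      prelims <- which(vapply(held, function(h) g %in% h$prelim, TRUE))
      fulls <- which(vapply(held, function(h) g %in% h$full, TRUE))
      expect_lte(length(fulls), 1L)
      expect_lte(length(prelims) + length(fulls), 1L)
      if (length(fulls)) {
        expect_length(readers, 0L)             # full write excludes reads
      }
      expect_lte(length(readers), 1L)          # one read-lock cell per gid
    }
  }
  for (i in 1:1000) {
    pid <- sample(2:9, 1L)
    g <- sample(10L, 1L)
    h <- held[[pid]]
    op <- sample(4L, 1L)
    if (op == 1L) {                            # read acquire / release
      if (g %in% h$read) {
        neurogrow:::lock_release(ls, pid, g, "read")
        held[[pid]]$read <- setdiff(h$read, g)
      } else if (neurogrow:::lock_acquire(ls, pid, g, "read", 3L)$ok) {
        held[[pid]]$read <- c(h$read, g)
      }
    } else if (op == 2L) {                     # preliminary write
      if (neurogrow:::lock_acquire(ls, pid, g, "prelim", 3L)$ok &&
          !(g %in% h$prelim)) {
        held[[pid]]$prelim <- c(h$prelim, g)
      }
    } else if (op == 3L && length(h$prelim)) { # upgrade to full
      g2 <- h$prelim[1L]
      if (neurogrow:::lock_acquire(ls, pid, g2, "full", 3L)$ok) {
        held[[pid]]$prelim <- setdiff(h$prelim, g2)
        held[[pid]]$full <- c(h$full, g2)
      }
    } else {                                   # release a write lock
      w <- c(h$prelim, h$full)
      if (length(w)) {
        g2 <- w[1L]
        neurogrow:::lock_release(ls, pid, g2, "write")
        held[[pid]]$prelim <- setdiff(h$prelim, g2)
        held[[pid]]$full <- setdiff(h$full, g2)
      }
    }
    check_tables()
  }
  # release everything still held, then audit the ledger
  for (pid in 2:9) {
    for (g in held[[pid]]$read) neurogrow:::lock_release(ls, pid, g, "read")
    for (g in c(held[[pid]]$prelim, held[[pid]]$full)) {
      neurogrow:::lock_release(ls, pid, g, "write")
    }
  }
  expect_true(all(ls$read_lock == 0L))
  expect_true(all(ls$write_lock == 0L))
  log <- do.call(rbind, lapply(ls$log, as.data.frame))
  grants <- log[log$action == "grant", ]
  releases <- log[log$action == "release", ]
  # full grants follow a prelim grant, so prelim grants = prelim releases +
  # full grants; overall every grant is balanced by a release or an upgrade
  expect_equal(nrow(grants[grants$mode == "read", ]),
               nrow(releases[releases$mode == "read", ]))
  expect_equal(nrow(grants[grants$mode == "prelim", ]),
               nrow(releases[releases$mode == "prelim", ]) +
                 nrow(grants[grants$mode == "full", ]))
  expect_equal(nrow(grants[grants$mode == "full", ]),
               nrow(releases[releases$mode == "full", ]))
})

test_that("private-section allocation reproduces the worked id sequence", {
  # two subclass rows, admin + 3 worker sections of 100 slots each
  st <- neurogrow:::new_front_store(2L, 4L, 100L)
  pair <- function(fid) c(neurogrow:::fid_row(st, fid),
                          neurogrow:::fid_index(st, fid))
  # admin (core 1) creates the three somata
  expect_equal(pair(neurogrow:::store_allocate(st, 1L, 1L)), c(1L, 1L))
  expect_equal(pair(neurogrow:::store_allocate(st, 1L, 1L)), c(1L, 2L))
  expect_equal(pair(neurogrow:::store_allocate(st, 1L, 2L)), c(2L, 1L))
  # cycle 1: cores 2, 3 make two subclass-1 children each, core 4 one of
  # subclass 2
  expect_equal(pair(neurogrow:::store_allocate(st, 2L, 1L)), c(1L, 101L))
  expect_equal(pair(neurogrow:::store_allocate(st, 2L, 1L)), c(1L, 102L))
  expect_equal(pair(neurogrow:::store_allocate(st, 3L, 1L)), c(1L, 201L))
  expect_equal(pair(neurogrow:::store_allocate(st, 3L, 1L)), c(1L, 202L))
  expect_equal(pair(neurogrow:::store_allocate(st, 4L, 2L)), c(2L, 301L))
  # cycle 2: three more children on core 2, one on core 3
  expect_equal(pair(neurogrow:::store_allocate(st, 2L, 1L)), c(1L, 103L))
  expect_equal(pair(neurogrow:::store_allocate(st, 3L, 1L)), c(1L, 203L))
  expect_equal(pair(neurogrow:::store_allocate(st, 2L, 1L)), c(1L, 104L))
  expect_equal(pair(neurogrow:::store_allocate(st, 2L, 1L)), c(1L, 105L))
  # overflow: filling a 100-slot section errors on the 101st
  st2 <- neurogrow:::new_front_store(1L, 2L, 100L)
  for (i in 1:100) neurogrow:::store_allocate(st2, 2L, 1L)
  expect_error(neurogrow:::store_allocate(st2, 2L, 1L), class = "overflowError")
  # rows are tracked independently per core
  expect_equal(pair(neurogrow:::store_allocate(st, 2L, 2L)), c(2L, 101L))
})

test_that("scripted dispatch reproduces the worked two-cycle story", {
  # subclass 1 somata branch twice then their children extend once;
  # subclass 2 somata make a single child
  t1 <- scripted_type("s1", 2L)
  t2 <- scripted_type("s2", 1L, extend = FALSE)
  sim <- new_simulation(c(-200, -200, -200), c(200, 200, 200), list(t1, t2),
                        seed = 1, num_workers = 3L, section_size = 100L)
  cap <- sim$store$capacity
  fid_of <- function(row, index) (row - 1L) * cap + index
  add_neurons(sim, "s1", "purple", soma_radius = 5, placement = "explicit",
              positions = matrix(c(-100, 0, 0), 1, 3))
  add_neurons(sim, "s1", "brown", soma_radius = 5, placement = "explicit",
              positions = matrix(c(0, 0, 0), 1, 3))
  add_neurons(sim, "s2", "pink", soma_radius = 5, placement = "explicit",
              positions = matrix(c(100, 0, 0), 1, 3))
  expect_equal(which(sim$store$used), c(fid_of(1, 1), fid_of(1, 2), fid_of(2, 1)))
  plan <- list(
    list(fid = c(fid_of(1, 1), fid_of(1, 2), fid_of(2, 1)), worker = c(1L, 2L, 3L)),
    list(fid = c(fid_of(1, 201), fid_of(1, 101), fid_of(2, 301),
                 fid_of(1, 102), fid_of(1, 202)),
         worker = c(1L, 2L, 3L, 1L, 1L))
  )
  simulation_loop(sim, 2, dispatch_plan = plan)
  got <- which(sim$store$used)
  want <- c(fid_of(1, 1), fid_of(1, 2),                    # somata (core 1)
            fid_of(1, 101), fid_of(1, 102),                # purple, core 2
            fid_of(1, 103), fid_of(1, 104), fid_of(1, 105),# cycle 2 on core 2
            fid_of(1, 201), fid_of(1, 202),                # brown, core 3
            fid_of(1, 203),                                # cycle 2 on core 3
            fid_of(2, 1), fid_of(2, 301))                  # pink soma + child
  expect_setequal(got, want)
  # lineage: (1,201) processed on core 2 made (1,103); (1,101) on core 3
  # made (1,203)
  expect_equal(sim$store$parent[fid_of(1, 103)], fid_of(1, 201))
  expect_equal(sim$store$parent[fid_of(1, 203)], fid_of(1, 101))
  expect_equal(sim$store$parent[fid_of(1, 104)], fid_of(1, 102))
  expect_equal(sim$store$parent[fid_of(1, 105)], fid_of(1, 202))
  expect_equal(sim$store$num_children[fid_of(2, 301)], 0L)
})

test_that("every scheduled front is dispatched exactly once per cycle", {
  sim <- new_simulation(c(-100, -100, -100), c(100, 100, 100),
                        list(scripted_type("t", 4L)), seed = 3,
                        num_workers = 4L)
  add_neurons(sim, "t", "n", n = 4, soma_radius = 5, placement = "explicit",
              positions = rbind(c(-60, -60, 0), c(60, -60, 0),
                                c(-60, 60, 0), c(60, 60, 0)))
  simulation_loop(sim, 3)
  log <- do.call(rbind, lapply(sim$dispatch_log, as.data.frame))
  log <- log[log$fid != neurogrow:::SENTINEL_FID, ]
  expect_false(any(duplicated(log[, c("cycle", "fid")])))
  # everything enabled at the start of a cycle was dispatched in it
  expect_equal(sum(log$cycle == 1L), 4L)       # the four somata
  expect_equal(sum(log$cycle == 2L), 16L)      # their 16 roots
})

test_that("created fronts always land in their creator's private section", {
  sim <- new_simulation(c(-100, -100, -100), c(100, 100, 100),
                        list(scripted_type("t", 4L)), seed = 5,
                        num_workers = 3L, section_size = 500L)
  somata <- add_neurons(sim, "t", "n", n = 3, soma_radius = 5,
                        placement = "explicit",
                        positions = rbind(c(-60, 0, 0), c(0, 0, 0), c(60, 0, 0)))
  simulation_loop(sim, 3)
  st <- sim$store
  section_of <- function(fid) {
    (neurogrow:::fid_index(st, fid) - 1L) %/% st$section_size + 1L
  }
  expect_true(all(vapply(somata, section_of, 0L) == 1L))  # admin section
  log <- do.call(rbind, lapply(sim$dispatch_log, as.data.frame))
  for (fid in setdiff(which(st$used), somata)) {
    par <- st$parent[fid]
    creator <- log$pid[log$cycle == st$birth_cycle[fid] & log$fid == par]
    expect_equal(section_of(fid), creator)
  }
})

test_that("fronts sharing grid points are never co-resident on two workers", {
  # two somata close enough to share gids, plus two far away
  sim <- new_simulation(c(-100, -100, -100), c(100, 100, 100),
                        list(scripted_type("t", 2L)), seed = 5,
                        num_workers = 2L)
  sim$locks$audit <- TRUE
  add_neurons(sim, "t", "n", n = 2, soma_radius = 4, placement = "explicit",
              positions = rbind(c(0, 0, 0), c(9, 0, 0)))
  add_neurons(sim, "t", "far", n = 1, soma_radius = 4, placement = "explicit",
              positions = matrix(c(-80, 0, 0), 1, 3))
  simulation_loop(sim, 2)
  for (snap in sim$slot_trace) {
    res1 <- snap[1, ][snap[1, ] > 0L]
    res2 <- snap[2, ][snap[2, ] > 0L]
    for (f1 in res1) for (f2 in res2) {
      g1 <- sim$fid_gids[[as.character(f1)]]
      g2 <- sim$fid_gids[[as.character(f2)]]
      expect_length(intersect(g1, g2), 0L)
    }
  }
})

test_that("worker prefetch keeps two ids queued while the backlog is large", {
  sim <- new_simulation(c(-200, -200, -200), c(200, 200, 200),
                        list(scripted_type("t", 4L)), seed = 8,
                        num_workers = 2L)
  sim$locks$audit <- TRUE
  pos <- as.matrix(expand.grid(x = c(-150, -50, 50, 150),
                               y = c(-150, -50, 50, 150), z = 0))
  add_neurons(sim, "t", "n", n = nrow(pos), soma_radius = 5,
              placement = "explicit", positions = pos)
  simulation_loop(sim, 1)
  fills <- vapply(sim$slot_trace, function(s) sum(s != 0L), 0L)
  # early snapshots: both workers hold two instructions (16 fronts, 2 workers)
  expect_true(any(fills == 4L))
  # a front is processed at most once even with prefetch
  log <- do.call(rbind, lapply(sim$dispatch_log, as.data.frame))
  log <- log[log$fid != neurogrow:::SENTINEL_FID, ]
  expect_false(any(duplicated(log[, c("cycle", "fid")])))
})
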