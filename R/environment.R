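# Substrate cues and synapses ---------------------------------------------------

#' Deposit diffusible substrate
#'
#' Places point sources of a named diffusible cue in the volume. Each source
#' releases `n_mol` molecules at its birth cycle and spreads with diffusion
#' constant `D`; growing fronts sense the resulting concentration field with
#' [sample_concentration()]. Fronts can also secrete substrate at their own
#' tip with [secrete_substrate()].
#'
#' @param sim a simulation object.
#' @param name substrate name.
#' @param positions an `n x 3` matrix (or length-3 vector) of source
#'   positions (um); an empty matrix is a no-op.
#' @param n_mol molecules released per source (`>= 0`).
#' @param D diffusion constant in um^2 per cycle (`> 0`).
#' @return invisibly, the number of sources added.
#' @export
deposit_substrate <- function(sim, name, positions, n_mol, D) {
  stopifnot(n_mol >= 0, D > 0)
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 3L, byrow = TRUE)
  if (!nrow(positions)) return(invisible(0L))
  for (i in seq_len(nrow(positions))) {
    if (!point_in_volume(sim, positions[i, ])) volume_error()
  }
  for (i in seq_len(nrow(positions))) {
    sim$substrate <- rbind(sim$substrate, data.frame(
      name = name, x = positions[i, 1], y = positions[i, 2],
      z = positions[i, 3], n_mol = n_mol, D = D,
      birth_cycle = sim$cycle, stringsAsFactors = FALSE))
    sim$pend_sub <- c(sim$pend_sub, nrow(sim$substrate))
    record_event(sim, list(symbol = "substrate", fid = 0L))
  }
  invisible(nrow(positions))
}

#' @rdname deposit_substrate
#' @param front a front id; the source is placed at the front's distal
#'   coordinate.
#' @export
secrete_substrate <- function(sim, front, name, n_mol, D) {
  if (!is.null(sim$current_front) && sim$current_front != front) not_self_error()
  deposit_substrate(sim, name, sim$store$end[front, ], n_mol, D)
}

#' Sample a substrate concentration
#'
#' Evaluates the concentration of a named substrate at a point, summing the
#' instantaneous point-source diffusion kernel
#' `C(r, t) = n_mol * (4 pi D t)^(-3/2) * exp(-r^2 / (4 D t))` over all
#' sources, with `t` the cycles elapsed since each source's birth (`t = 0`
#' is treated as `t = 1`, i.e. one cycle of spreading). In stochastic mode --
#' the default, emulating the noisy sensing of a growth cone -- the return
#' value is a Poisson draw of the molecule count in a 1 um^3 probe volume
#' with that mean.
#'
#' @param sim a simulation object.
#' @param point numeric length-3 probe position (um).
#' @param name substrate name.
#' @param stochastic if `TRUE`, return a Poisson molecule count; if `FALSE`,
#'   the deterministic mean.
#' @return a non-negative number (count if stochastic).
#' @export
sample_concentration <- function(sim, point, name, stochastic = TRUE) {
  src <- sim$substrate[sim$substrate$name == name, , drop = FALSE]
  if (!nrow(src)) return(0)
  t <- pmax(sim$cycle - src$birth_cycle, 1)
  r2 <- (point[1] - src$x)^2 + (point[2] - src$y)^2 + (point[3] - src$z)^2
  mean_c <- sum(src$n_mol * (4 * pi * src$D * t)^(-1.5) * exp(-r2 / (4 * src$D * t)))
  if (stochastic) stats::rpois(1L, mean_c) else mean_c
}

#' Create a synapse between two nearby fronts
#'
#' Records a synapse from a presynaptic to a postsynaptic front. Synapses do
#' not occupy space (no grid registration), but the two fronts must be close:
#' their surface-to-surface distance (axis distance minus both radii) must
#' not exceed `max_distance`. Retraction of either front removes the synapse
#' at the end of that cycle.
#'
#' @param sim a simulation object.
#' @param pre,post front ids of the pre- and postsynaptic fronts.
#' @param weight initial synaptic weight.
#' @param max_distance maximum surface-to-surface separation (um).
#' @return the synapse row index, invisibly.
#' @export
add_synapse <- function(sim, pre, post, weight = 1, max_distance = 0.5) {
  st <- sim$store
  if (pre == post) usage_error("add_synapse: pre and post must differ")
  if (!st$used[pre] || st$retracted[pre] || !st$used[post] || st$retracted[post]) {
    usage_error("add_synapse: both fronts must be live")
  }
  live <- is.na(sim$synapses$death_cycle)
  if (any(live & sim$synapses$pre == pre & sim$synapses$post == post)) {
    usage_error("add_synapse: duplicate pre/post pair")
  }
  a <- front_axis(st, pre); b <- front_axis(st, post)
  d <- seg_dist_many(a$p0, a$p1,
                     matrix(b$p0, 1L, 3L, byrow = TRUE),
                     matrix(b$p1, 1L, 3L, byrow = TRUE))[1L]
  gap <- d - st$radius[pre] - st$radius[post]
  if (gap > max_distance) {
    usage_error(sprintf(
      "add_synapse: fronts are %.2f um apart (max %.2f)", gap, max_distance))
  }
  sim$synapses <- rbind(sim$synapses, data.frame(
    pre = pre, post = post, weight = weight,
    birth_cycle = sim$cycle, death_cycle = NA_integer_))
  sim$pend_syn <- c(sim$pend_syn, nrow(sim$synapses))
  record_event(sim, list(symbol = "synapse", fid = pre))
  invisible(nrow(sim$synapses))
}

#' Count live synapses on a front or branch
#'
#' Number of live synapses whose pre- or postsynaptic front is the given
#' front, or lies anywhere on its branch (the front plus all descendants)
#' when `branch = TRUE`.
#'
#' @param sim a simulation object.
#' @param fid front id.
#' @param branch count over the whole subtree rooted at `fid`?
#' @return an integer count.
#' @export
count_synapses <- function(sim, fid, branch = FALSE) {
  fids <- if (branch) collect_branch(sim$store, fid) else fid
  syn <- sim$synapses
  live <- is.na(syn$death_cycle)
  sum(live & (syn$pre %in% fids | syn$post %in% fids))
}

#' Hebbian synaptic weight update
#'
#' The simple rate-product Hebbian rule:
#' `weight' = weight + learning_rate * pre_rate * post_rate`. Neurons carry a
#' firing rate, so correlated pre/post activity potentiates the synapse; a
#' zero rate on either side leaves the weight unchanged.
#'
#' @param weight current weight.
#' @param pre_rate,post_rate non-negative firing rates.
#' @param learning_rate learning rate.
#' @return the updated weight.
#' @export
hebbian_update <- function(weight, pre_rate, post_rate, learning_rate) {
  stopifnot(pre_rate >= 0, post_rate >= 0)
  weight + learning_rate * pre_rate * post_rate
}

#' Live synapse table
#'
#' @param sim a simulation object.
#' @param live_only drop synapses removed by retraction?
#' @return a `data.frame` with columns `pre`, `post`, `weight`,
#'   `birth_cycle`, `death_cycle`.
#' @export
synapse_table <- function(sim, live_only = TRUE) {
  syn <- sim$synapses
  if (live_only) syn <- syn[is.na(syn$death_cycle), , drop = FALSE]
  syn
}
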