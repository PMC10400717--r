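#' Simulation error conditions
#'
#' All recoverable simulation failures are signalled as classed conditions so
#' that growth rules can catch exactly the failure modes they expect, in the
#' style of `tryCatch(add_child(...), collisionError = ...)`. Every condition
#' inherits from `"ng_error"`; the subclasses are:
#'
#' * `collisionError` -- the proposed structure overlaps an existing front;
#'   carries `colliding`, the id of the first colliding front found.
#' * `insideParentError` -- the proposed position lies inside the parent.
#' * `volumeError` -- a coordinate falls outside the simulation volume.
#' * `gridCompetitionError` -- a grid lock could not be obtained before the
#'   timeout; typically handled by retrying now or during the next cycle.
#' * `overflowError` -- a fixed-size shared array section is exhausted;
#'   carries `array_name`. Enlarge the corresponding capacity.
#' * `notSelfError` -- a front method was invoked on a front other than the
#'   one currently dispatched for processing.
#' * `usageError` -- an API contract violation (e.g. retracting a non-terminal
#'   front with the single-front call).
#'
#' @param message human-readable description.
#' @param class condition subclass.
#' @param ... extra fields stored on the condition object.
#' @return These functions do not return; they signal a condition.
#' @keywords internal
#' @name ng_errors
NULL

ng_stop <- function(class, message, ...) {
  cond <- structure(
    class = c(class, "ng_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

collision_error <- function(colliding, message = NULL) {
  if (is.null(message)) {
    message <- sprintf("collision with front %s", format_fid(colliding))
  }
  ng_stop("collisionError", message, colliding = colliding)
}

inside_parent_error <- function(message = "new position lies inside the parent") {
  ng_stop("insideParentError", message)
}

volume_error <- function(message = "coordinate outside the simulation volume") {
  ng_stop("volumeError", message)
}

grid_competition_error <- function(gid, message = NULL) {
  if (is.null(message)) {
    message <- sprintf("could not lock grid point %d before timeout", gid)
  }
  ng_stop("gridCompetitionError", message, gid = gid)
}

overflow_error <- function(array_name) {
  ng_stop("overflowError",
          sprintf("shared array '%s' is full; increase its capacity", array_name),
          array_name = array_name)
}

not_self_error <- function(message = "front method called on a front other than self") {
  ng_stop("notSelfError", message)
}

usage_error <- function(message) {
  ng_stop("usageError", message)
}
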