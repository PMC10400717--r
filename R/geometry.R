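#' Minimum distance between two 3D line segments
#'
#' Computes the minimum Euclidean distance between the closed segments
#' `p0`--`p1` and `q0`--`q1`, the primitive underlying capsule collision
#' detection: two capsule-shaped fronts overlap iff the distance between
#' their axis segments is smaller than the sum of their radii. Zero-length
#' segments are allowed and reduce to point--segment or point--point
#' distance, which is how spherical somata (a degenerate segment plus a
#' radius) share the collision code with cylinders.
#'
#' The implementation is the standard clamped closest-point parameterisation
#' for a pair of segments (the classic `dist3D_Segment_to_Segment` approach).
#'
#' @param p0,p1 numeric length-3, endpoints of the first segment (um).
#' @param q0,q1 numeric length-3, endpoints of the second segment (um).
#' @return single numeric distance in um; symmetric in the segment order.
#' @examples
#' segment_segment_distance(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
#' @export
segment_segment_distance <- function(p0, p1, q0, q1) {
  seg_dist_many(p0, p1,
                matrix(q0, 1L, 3L, byrow = TRUE),
                matrix(q1, 1L, 3L, byrow = TRUE))[1L]
}

# Vectorised segment distance: one segment (p0, p1) against n segments given
# as n x 3 matrices Q0, Q1. Used in collision queries and invariant sweeps.
seg_dist_many <- function(p0, p1, Q0, Q1) {
  n <- nrow(Q0)
  if (n == 0L) return(numeric(0))
  u <- p1 - p0                                  # direction of segment 1
  V <- Q1 - Q0                                  # directions of segments 2
  W <- matrix(p0, n, 3L, byrow = TRUE) - Q0     # q0 -> p0
  if (sum(u * u) < 1e-24) {
    # degenerate first segment: point-to-segment closed form
    return(point_seg_dist_many(p0, Q0, Q1))
  }
  a <- sum(u * u)
  b <- as.numeric(V %*% u)
  c_ <- rowSums(V * V)
  d <- as.numeric(W %*% u)
  e <- rowSums(V * W)
  D <- a * c_ - b * b
  eps <- 1e-12 * max(a, max(c_, 0), 1)

  sN <- numeric(n); sD <- D
  tN <- numeric(n); tD <- D

  par <- D <= eps                               # (near-)parallel or degenerate
  sN[par] <- 0; sD[par] <- 1
  tN[par] <- e[par]; tD[par] <- c_[par]
  np <- !par
  sN[np] <- b[np] * e[np] - c_[np] * d[np]
  tN[np] <- a * e[np] - b[np] * d[np]
  # clamp s to [0, 1] (re-deriving t on the clamped edge)
  lo <- np & sN < 0
  sN[lo] <- 0; tN[lo] <- e[lo]; tD[lo] <- c_[lo]
  hi <- np & sN > sD
  sN[hi] <- sD[hi]; tN[hi] <- e[hi] + b[hi]; tD[hi] <- c_[hi]

  # clamp t to [0, 1], re-deriving s on the clamped edge
  tlo <- tN < 0
  tN[tlo] <- 0
  i1 <- tlo & (-d < 0);           sN[i1] <- 0
  i2 <- tlo & (-d > a);           sN[i2] <- sD[i2]
  i3 <- tlo & !( -d < 0) & !(-d > a)
  sN[i3] <- -d[i3]; sD[i3] <- a
  thi <- tN > tD
  tN[thi] <- tD[thi]
  j1 <- thi & ((-d + b) < 0);     sN[j1] <- 0
  j2 <- thi & ((-d + b) > a);     sN[j2] <- sD[j2]
  j3 <- thi & !((-d + b) < 0) & !((-d + b) > a)
  sN[j3] <- -d[j3] + b[j3]; sD[j3] <- a

  sc <- ifelse(abs(sN) <= eps | sD == 0, 0, sN / sD)
  tc <- ifelse(abs(tN) <= eps | tD == 0, 0, tN / tD)

  dP <- W + outer(sc, u) - V * tc
  out <- sqrt(rowSums(dP * dP))
  # degenerate second segments: point q0 against segment p0-p1
  deg <- c_ < 1e-24
  if (any(deg)) {
    Wd <- W[deg, , drop = FALSE]
    a_ <- sum(u * u)
    t <- pmin(pmax(-as.numeric(Wd %*% u) / a_, 0), 1)
    dPd <- Wd + outer(t, u)
    out[deg] <- sqrt(rowSums(dPd * dPd))
  }
  out
}

# Distance from one point to n segments (closed form), n x 3 matrices.
point_seg_dist_many <- function(p, Q0, Q1) {
  V <- Q1 - Q0
  W <- matrix(p, nrow(Q0), 3L, byrow = TRUE) - Q0
  c2 <- rowSums(V * V)
  t <- ifelse(c2 > 0, pmin(pmax(rowSums(W * V) / pmax(c2, 1e-300), 0), 1), 0)
  dP <- W - V * t
  sqrt(rowSums(dP * dP))
}

#' Sample a unit direction within a cone around a heading
#'
#' Draws a pseudo-random unit vector whose angle to `heading` is at most
#' `max_angle` degrees, used by growth rules to extend a neurite within a
#' cone around its current direction. The draw is uniform in solid angle on
#' the spherical cap, so directions near the cone edge are not
#' over-represented relative to their area.
#'
#' @param heading numeric length-3 unit vector, the current direction.
#' @param max_angle cone half-angle in degrees, in `[0, 180]`. `0` returns
#'   `heading` exactly; `180` is a uniform draw on the whole sphere.
#' @return a unit-norm numeric length-3 vector.
#' @examples
#' set.seed(1)
#' v <- unit_heading_sample(c(0, 0, 1), 20)
#' acos(v[3]) * 180 / pi  # <= 20
#' @export
unit_heading_sample <- function(heading, max_angle) {
  stopifnot(length(heading) == 3L, is.finite(max_angle),
            max_angle >= 0, max_angle <= 180)
  h <- heading / sqrt(sum(heading^2))
  if (max_angle == 0) return(h)
  cos_max <- cos(max_angle * pi / 180)
  z <- stats::runif(1L, cos_max, 1)            # uniform in solid angle
  phi <- stats::runif(1L, 0, 2 * pi)
  r <- sqrt(pmax(1 - z * z, 0))
  local <- c(r * cos(phi), r * sin(phi), z)
  rotate_z_to(local, h)
}

# Rotate vector v (expressed with +z as reference) so +z maps onto axis.
rotate_z_to <- function(v, axis) {
  z <- c(0, 0, 1)
  d <- sum(z * axis)
  if (d > 1 - 1e-12) return(v)
  if (d < -1 + 1e-12) return(c(v[1], -v[2], -v[3]))  # 180 deg about x
  k <- c(z[2] * axis[3] - z[3] * axis[2],
         z[3] * axis[1] - z[1] * axis[3],
         z[1] * axis[2] - z[2] * axis[1])
  k <- k / sqrt(sum(k^2))
  cth <- d; sth <- sqrt(pmax(1 - d * d, 0))
  # Rodrigues rotation
  v * cth + cross3(k, v) * sth + k * sum(k * v) * (1 - cth)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Sample well-separated unit directions around a point
#'
#' Draws `n` unit vectors uniformly on the sphere, rejecting draws until all
#' pairwise angular separations are at least `min_separation` degrees.
#' Growth rules use this to propose candidate directions for dendritic roots
#' or branch children around a soma or branch point; requesting more
#' candidates than needed makes root creation robust in crowded volumes.
#'
#' @param n number of directions, `n >= 1`.
#' @param min_separation minimum pairwise angle in degrees; the default
#'   `180 / n` keeps the constraint feasible for any `n`.
#' @param max_tries rejection budget before giving up.
#' @return an `n x 3` matrix of unit row vectors.
#' @export
unit_branching_sample <- function(n, min_separation = 180 / n, max_tries = 1000L) {
  stopifnot(n >= 1, min_separation >= 0)
  cos_sep <- cos(min_separation * pi / 180)
  for (i in seq_len(max_tries)) {
    z <- stats::runif(n, -1, 1)
    phi <- stats::runif(n, 0, 2 * pi)
    r <- sqrt(pmax(1 - z * z, 0))
    pts <- cbind(r * cos(phi), r * sin(phi), z)
    if (n == 1L) return(pts)
    g <- pts %*% t(pts)
    if (max(g[upper.tri(g)]) <= cos_sep + 1e-12) return(pts)
  }
  usage_error(sprintf(
    "could not sample %d directions separated by %.1f degrees in %d tries",
    n, min_separation, max_tries))
}

#' Compute a tapered child radius
#'
#' Returns `parent_radius * factor`, the radius given to branch children so
#' that neurites thin out with branch order.
#'
#' @param parent_radius parent radius in um, `> 0`.
#' @param factor multiplicative taper in `(0, 1]`; default 0.9.
#' @return child radius in um.
#' @export
taper <- function(parent_radius, factor = 0.9) {
  if (!is.finite(parent_radius) || parent_radius <= 0) {
    usage_error("taper: parent_radius must be positive")
  }
  if (!is.finite(factor) || factor <= 0 || factor > 1) {
    usage_error("taper: factor must be in (0, 1]")
  }
  parent_radius * factor
}

norm3 <- function(v) sqrt(sum(v * v))
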