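#' Wrap angles onto the principal circle
#'
#' Maps arbitrary real angles to the half-open interval (-pi, pi]. All
#' headings and heading changes in the package are stored in this
#' convention.
#'
#' @param theta numeric vector of angles in radians.
#' @return numeric vector of the same length, each element in (-pi, pi].
#' @export
#' @examples
#' wrap_angle(c(0, 3 * pi / 2, -pi, pi, 2 * pi))
wrap_angle <- function(theta) {
  out <- theta
  idx <- !is.na(theta) & (theta <= -pi | theta > pi)
  out[idx] <- -((pi - theta[idx]) %% (2 * pi) - pi)
  out
}

#' Shortest displacement under periodic boundaries
#'
#' Computes the minimum-image displacement from point `a` to point `b` in a
#' square periodic arena of side `arena_size`: the shortest of the nine
#' displacements obtained by translating `b` through all periodic images.
#'
#' @param a,b numeric length-2 coordinate vectors, or two-column matrices of
#'   coordinates (recycled row-wise against each other).
#' @param arena_size side length of the periodic box; must be positive.
#' @return displacement from `a` to `b`, same shape as the inputs, with each
#'   component in `[-arena_size / 2, arena_size / 2)`.
#' @export
#' @examples
#' minimum_image_displacement(c(9, 5), c(1, 5), 10) # c(2, 0), not c(-8, 0)
minimum_image_displacement <- function(a, b, arena_size) {
  if (!is.numeric(arena_size) || length(arena_size) != 1L || arena_size <= 0) {
    abort("`arena_size` must be a single positive number.")
  }
  d <- b - a
  (d + arena_size / 2) %% arena_size - arena_size / 2
}

## Pairwise minimum-image geometry for a single swarm state.
## Returns N x N matrices: dx/dy (displacement from focal i to j), dist,
## and rel_bearing (bearing of j relative to focal i's heading, in (-pi, pi]).
## The diagonal carries dist = Inf so the focal particle never selects itself.
pairwise_geometry <- function(x, y, heading, arena_size) {
  n <- length(x)
  dx <- minimum_image_displacement(matrix(x, n, n), matrix(x, n, n, byrow = TRUE), arena_size)
  dy <- minimum_image_displacement(matrix(y, n, n), matrix(y, n, n, byrow = TRUE), arena_size)
  dist <- sqrt(dx^2 + dy^2)
  diag(dist) <- Inf
  rel_bearing <- wrap_angle(atan2(dy, dx) - matrix(heading, n, n))
  list(dx = dx, dy = dy, dist = dist, rel_bearing = rel_bearing)
}
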