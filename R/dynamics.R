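## ---- internal state representation -------------------------------------
## Public objects are tidy tibbles (t, particle, x, y, heading); the hot
## loops work on plain column vectors extracted once.

traj_attr_names <- c("arena_size", "params", "spec", "seed")

new_swarm_trajectory <- function(df, arena_size, params = NULL, spec = NULL,
                                 seed = NULL) {
  out <- tibble::as_tibble(df)
  attr(out, "arena_size") <- arena_size
  attr(out, "params") <- params
  attr(out, "spec") <- spec
  attr(out, "seed") <- seed
  class(out) <- c("swarm_trajectory", class(tibble::tibble()))
  out
}

#' Arena size of a trajectory or state
#'
#' @param x a swarm trajectory or state tibble.
#' @param arena_size optional explicit override.
#' @return the side length of the periodic arena.
#' @export
arena_size_of <- function(x, arena_size = NULL) {
  if (!is.null(arena_size)) {
    return(arena_size)
  }
  a <- attr(x, "arena_size", exact = TRUE)
  if (is.null(a)) {
    abort(paste0(
      "No `arena_size` attribute found; pass `arena_size` explicitly or use ",
      "a state produced by simulate_swarm()/read_trajectory()."
    ))
  }
  a
}

## one-timestep tibble -> list(t, x, y, heading) ordered by particle id
st_cols <- function(state, arena_size = NULL) {
  need <- c("particle", "x", "y", "heading")
  if (!all(need %in% names(state))) {
    abort("A swarm state needs columns `particle`, `x`, `y`, `heading`.")
  }
  if ("t" %in% names(state) && length(unique(state$t)) > 1L) {
    abort("A swarm state must contain a single timestep; use state_at().")
  }
  ord <- order(state$particle)
  list(
    t = if ("t" %in% names(state)) state$t[ord][1] else 0L,
    x = state$x[ord], y = state$y[ord],
    heading = state$heading[ord],
    arena_size = arena_size_of(state, arena_size)
  )
}

#' Extract one timestep from a trajectory
#'
#' @param traj a swarm trajectory tibble.
#' @param t timestep to extract (values of the `t` column).
#' @return a single-state tibble carrying the trajectory's metadata.
#' @export
state_at <- function(traj, t) {
  if (!t %in% traj$t) {
    abort(paste0("Timestep ", t, " is not present in the trajectory."))
  }
  out <- traj[traj$t == t, , drop = FALSE]
  for (a in traj_attr_names) attr(out, a) <- attr(traj, a, exact = TRUE)
  out
}

## ---- neighbourhoods ------------------------------------------------------

## N x N logical neighbour mask (row = focal) for one parameter combination.
## Visibility: particle j is visible from i iff the bearing of j relative to
## i's heading has magnitude <= pi - blind_angle / 2 (blind_angle is the
## TOTAL width of the rear blind sector).
neighbour_mask <- function(geom, scheme, blind_angle, radius = NULL, k = NULL) {
  n <- nrow(geom$dist)
  vis <- abs(geom$rel_bearing) <= pi - blind_angle / 2
  diag(vis) <- FALSE
  if (scheme == "geometric") {
    return(vis & geom$dist <= radius)
  }
  ## topological: k nearest visible, distance ties broken by particle index
  m <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    d <- geom$dist[i, ]
    d[!vis[i, ]] <- Inf
    take <- min(k, sum(is.finite(d)))
    if (take > 0) {
      m[i, order(d, seq_len(n))[seq_len(take)]] <- TRUE
    }
  }
  m
}

#' Interaction neighbourhood of a particle
#'
#' Returns the particles the focal particle interacts with under the given
#' rules: never itself; never particles inside the rear blind sector; and,
#' under the geometric scheme, only particles within `interaction_radius`
#' (minimum-image distance), or, under the topological scheme, the
#' `neighbour_count` nearest visible particles (fewer if fewer are
#' visible).
#'
#' @param state a single-timestep swarm state tibble.
#' @param focal particle id of the focal individual.
#' @param params a [model_params()] object.
#' @param spec a [model_spec()] object (defaults to the geometric,
#'   attraction + alignment variant).
#' @param arena_size optional override of the state's arena size.
#' @return integer vector of neighbour particle ids (possibly empty).
#' @export
neighbourhood <- function(state, focal, params, spec = model_spec(),
                          arena_size = NULL) {
  st <- st_cols(state, arena_size)
  n <- length(st$x)
  ids <- sort(state$particle)
  fi <- match(focal, ids)
  if (is.na(fi)) abort("`focal` is not a particle id in `state`.")
  geom <- pairwise_geometry(st$x, st$y, st$heading, st$arena_size)
  m <- neighbour_mask(geom, spec$neighbourhood, params$blind_angle,
    radius = params$interaction_radius, k = params$neighbour_count
  )
  ids[which(m[fi, ])]
}

## ---- social forces -------------------------------------------------------

unitize_rows <- function(vx, vy, tol = 1e-12) {
  nrm <- sqrt(vx^2 + vy^2)
  bad <- nrm < tol
  nrm[bad] <- 1
  vx <- vx / nrm
  vy <- vy / nrm
  vx[bad] <- 0
  vy[bad] <- 0
  list(x = vx, y = vy, zero = bad)
}

## alignment / attraction unit vectors for ALL particles given a mask
social_vectors_all <- function(st, mask) {
  ux <- cos(st$heading)
  uy <- sin(st$heading)
  geom <- st$geom
  a <- unitize_rows(as.numeric(mask %*% ux), as.numeric(mask %*% uy))
  c_ <- unitize_rows(rowSums(mask * geom$dx), rowSums(mask * geom$dy))
  list(align = a, attract = c_)
}

#' Alignment and attraction vectors of a focal particle
#'
#' The alignment vector is the unit-normalised sum of the neighbours'
#' heading unit vectors; the attraction vector is the unit-normalised
#' minimum-image displacement from the focal particle to the neighbours'
#' centre of mass (computed in minimum-image coordinates relative to the
#' focal particle). Either is `NULL` when the neighbour set is empty or the
#' vector being normalised has zero length.
#'
#' @inheritParams neighbourhood
#' @param neighbours integer vector of neighbour particle ids (for example
#'   from [neighbourhood()]); must not contain `focal`.
#' @return a list with elements `alignment` and `attraction`, each a length-2
#'   unit vector or `NULL`.
#' @export
social_vectors <- function(state, focal, neighbours, arena_size = NULL) {
  if (focal %in% neighbours) abort("`neighbours` must not contain `focal`.")
  st <- st_cols(state, arena_size)
  ids <- sort(state$particle)
  fi <- match(focal, ids)
  ni <- match(neighbours, ids)
  if (anyNA(c(fi, ni))) abort("Unknown particle id in `focal` or `neighbours`.")
  if (length(ni) == 0L) {
    return(list(alignment = NULL, attraction = NULL))
  }
  a <- c(sum(cos(st$heading[ni])), sum(sin(st$heading[ni])))
  dx <- minimum_image_displacement(st$x[fi], st$x[ni], st$arena_size)
  dy <- minimum_image_displacement(st$y[fi], st$y[ni], st$arena_size)
  cc <- c(mean(dx), mean(dy))
  norm_or_null <- function(v) {
    nr <- sqrt(sum(v^2))
    if (nr < 1e-12) NULL else v / nr
  }
  list(alignment = norm_or_null(a), attraction = norm_or_null(cc))
}

## ---- direction update ----------------------------------------------------

## deterministic predicted headings for ALL particles (no noise); the core
## direction rule: normalise(inertia + alignment_weight * A + attraction_weight * C)
predicted_headings_all <- function(st, mask, attraction_weight, alignment_weight) {
  sv <- social_vectors_all(st, mask)
  vx <- cos(st$heading) + alignment_weight * sv$align$x + attraction_weight * sv$attract$x
  vy <- sin(st$heading) + alignment_weight * sv$align$y + attraction_weight * sv$attract$y
  out <- atan2(vy, vx)
  degenerate <- vx^2 + vy^2 < 1e-24
  out[degenerate] <- st$heading[degenerate]
  out
}

st_with_geom <- function(state, arena_size = NULL) {
  st <- st_cols(state, arena_size)
  st$geom <- pairwise_geometry(st$x, st$y, st$heading, st$arena_size)
  st
}

#' Deterministic predicted heading of a particle
#'
#' The noise-free direction a particle would adopt at the next step: the
#' angle of `inertia + alignment_weight * A + attraction_weight * C`, where
#' the inertia term is the current heading unit vector and `A`, `C` are the
#' (unit) alignment and attraction vectors over the current neighbourhood.
#' A force excluded by the model or undefined (empty neighbourhood,
#' zero-length sum) contributes nothing; when the whole sum vanishes the
#' current heading is kept.
#'
#' @inheritParams neighbourhood
#' @param focal particle id, or a vector of ids.
#' @return predicted heading angle(s) in (-pi, pi].
#' @export
predicted_direction <- function(state, focal, params, spec = model_spec(),
                                arena_size = NULL) {
  st <- st_with_geom(state, arena_size)
  ids <- sort(state$particle)
  fi <- match(focal, ids)
  if (anyNA(fi)) abort("`focal` is not a particle id in `state`.")
  mask <- neighbour_mask(st$geom, spec$neighbourhood, params$blind_angle,
    radius = params$interaction_radius, k = params$neighbour_count
  )
  wa <- if (spec$attraction) params$attraction_weight else 0
  wl <- if (spec$alignment) params$alignment_weight else 0
  predicted_headings_all(st, mask, wa, wl)[fi]
}

## ---- stepping ------------------------------------------------------------

## One synchronous update of the internal state. Consumes RNG in a fixed
## order: update indicators first (runif(n)), then angular noise (rnorm(n)).
step_internal <- function(st, params, spec) {
  n <- length(st$x)
  st$geom <- pairwise_geometry(st$x, st$y, st$heading, st$arena_size)
  mask <- neighbour_mask(st$geom, spec$neighbourhood, params$blind_angle,
    radius = params$interaction_radius, k = params$neighbour_count
  )
  wa <- if (spec$attraction) params$attraction_weight else 0
  wl <- if (spec$alignment) params$alignment_weight else 0
  pred <- predicted_headings_all(st, mask, wa, wl)
  updates <- runif(n) < params$update_prob
  noise <- rwrapnorm(n, params$noise_sd)
  new_heading <- wrap_angle(ifelse(updates, pred, st$heading) + noise)
  list(
    t = st$t + 1L,
    x = (st$x + params$speed * cos(new_heading)) %% st$arena_size,
    y = (st$y + params$speed * sin(new_heading)) %% st$arena_size,
    heading = new_heading,
    arena_size = st$arena_size
  )
}

#' Advance a swarm state by one timestep
#'
#' Synchronous update: every particle reads the input state. With
#' probability `update_prob` a particle adopts its [predicted_direction()],
#' otherwise it retains its previous heading; wrapped-Gaussian noise
#' (`noise_sd`) is then added in either case, and the particle moves
#' `speed` along its new heading, wrapping at the periodic boundary.
#'
#' @inheritParams neighbourhood
#' @return the state tibble at the next timestep.
#' @export
step_swarm <- function(state, params, spec = model_spec(), arena_size = NULL) {
  st <- st_cols(state, arena_size)
  nxt <- step_internal(st, params, spec)
  new_swarm_trajectory(
    tibble::tibble(
      t = nxt$t, particle = seq_along(nxt$x),
      x = nxt$x, y = nxt$y, heading = nxt$heading
    ),
    arena_size = st$arena_size, params = params, spec = spec
  )
}

#' Simulate a swarm trajectory
#'
#' Runs the self-propelled particle model for `n_steps` synchronous updates
#' from either a supplied initial state or a random configuration
#' (positions uniform over the arena, headings uniform on (-pi, pi]).
#'
#' @param params a [model_params()] object.
#' @param n_steps number of update steps; the returned trajectory has
#'   `n_steps + 1` timesteps including the initial state.
#' @param n_particles number of particles (ignored when `init` is given).
#' @param spec a [model_spec()] object.
#' @param init optional initial state tibble (columns `particle`, `x`, `y`,
#'   `heading`); its timestep is re-labelled 0.
#' @param seed optional integer seed; when given, the run is exactly
#'   reproducible and the seed is recorded on the trajectory.
#' @return a `swarm_trajectory` tibble with columns `t`, `particle`, `x`,
#'   `y`, `heading` and attributes `arena_size`, `params`, `spec`, `seed`.
#' @export
#' @examples
#' traj <- simulate_swarm(
#'   model_params(attraction_weight = 1, interaction_radius = 2),
#'   n_steps = 10, n_particles = 8, seed = 1
#' )
#' dplyr::count(traj, t)
simulate_swarm <- function(params, n_steps, n_particles = 25,
                           spec = model_spec(), init = NULL, seed = NULL) {
  stopifnot(n_steps >= 0, n_particles >= 1)
  if (!is.null(seed)) set.seed(seed)
  L <- params$arena_size
  if (is.null(init)) {
    st <- list(
      t = 0L,
      x = runif(n_particles, 0, L), y = runif(n_particles, 0, L),
      heading = wrap_angle(runif(n_particles, -pi, pi)),
      arena_size = L
    )
  } else {
    stc <- st_cols(init, arena_size = L)
    st <- list(t = 0L, x = stc$x, y = stc$y, heading = stc$heading, arena_size = L)
    n_particles <- length(st$x)
  }
  n_t <- n_steps + 1L
  X <- matrix(NA_real_, n_particles, n_t)
  Y <- matrix(NA_real_, n_particles, n_t)
  H <- matrix(NA_real_, n_particles, n_t)
  X[, 1] <- st$x
  Y[, 1] <- st$y
  H[, 1] <- st$heading
  if (n_steps > 0) {
    for (k in seq_len(n_steps)) {
      st <- step_internal(st, params, spec)
      X[, k + 1] <- st$x
      Y[, k + 1] <- st$y
      H[, k + 1] <- st$heading
    }
  }
  new_swarm_trajectory(
    tibble::tibble(
      t = rep(0:(n_t - 1L), each = n_particles),
      particle = rep(seq_len(n_particles), n_t),
      x = as.numeric(X), y = as.numeric(Y), heading = as.numeric(H)
    ),
    arena_size = L, params = params, spec = spec, seed = seed
  )
}

## ---- order parameter and steady state ------------------------------------

#' Milling order parameter
#'
#' Unsigned tangential order of a swarm state: the mean over particles of
#' `|sin(angle between the heading and the vector from the group centroid
#' to the particle)|`. Equals 1 for perfect tangential (milling) motion in
#' either or both rotational senses — rotating mills here routinely mix
#' clockwise and anti-clockwise particles — 0 for purely radial motion, and
#' about `2 / pi` in expectation for uniformly random headings. The
#' centroid is the circular mean of each coordinate, which is well defined
#' under periodic boundaries for a compact group.
#'
#' @inheritParams neighbourhood
#' @return a scalar in `[0, 1]`.
#' @export
milling_order <- function(state, arena_size = NULL) {
  st <- st_cols(state, arena_size)
  n <- length(st$x)
  if (n < 2) abort("milling_order() needs at least 2 particles.")
  L <- st$arena_size
  circ_mean_coord <- function(z) {
    ang <- 2 * pi * z / L
    (atan2(mean(sin(ang)), mean(cos(ang))) * L / (2 * pi)) %% L
  }
  cx <- circ_mean_coord(st$x)
  cy <- circ_mean_coord(st$y)
  rx <- minimum_image_displacement(cx, st$x, L)
  ry <- minimum_image_displacement(cy, st$y, L)
  radial <- atan2(ry, rx)
  mean(abs(sin(st$heading - radial)))
}

#' Run a swarm into the rotating-mill steady state
#'
#' Simulates until the [milling_order()] stays above `threshold` for
#' `window` consecutive steps (or `max_steps` is exhausted).
#'
#' @inheritParams simulate_swarm
#' @param threshold milling-order level that counts as milling.
#' @param window number of consecutive above-threshold steps required.
#' @param max_steps burn-in horizon.
#' @return a list with elements `state` (the final state tibble), `reached`
#'   (logical), `steps` (number of steps simulated) and `milling_order`
#'   (the final value).
#' @export
steady_state_swarm <- function(params, n_particles = 25, spec = model_spec(),
                               seed = NULL, threshold = 0.8, window = 10,
                               max_steps = 3000, init = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- params$arena_size
  if (is.null(init)) {
    st <- list(
      t = 0L,
      x = runif(n_particles, 0, L), y = runif(n_particles, 0, L),
      heading = wrap_angle(runif(n_particles, -pi, pi)),
      arena_size = L
    )
  } else {
    stc <- st_cols(init, arena_size = L)
    st <- list(t = 0L, x = stc$x, y = stc$y, heading = stc$heading, arena_size = L)
  }
  as_state <- function(s) {
    new_swarm_trajectory(
      tibble::tibble(
        t = s$t, particle = seq_along(s$x),
        x = s$x, y = s$y, heading = s$heading
      ),
      arena_size = L, params = params, spec = spec, seed = seed
    )
  }
  run <- 0L
  mo <- milling_order(as_state(st))
  for (k in seq_len(max_steps)) {
    st <- step_internal(st, params, spec)
    mo <- milling_order(as_state(st))
    run <- if (mo > threshold) run + 1L else 0L
    if (run >= window) {
      return(list(state = as_state(st), reached = TRUE, steps = k, milling_order = mo))
    }
  }
  list(state = as_state(st), reached = FALSE, steps = max_steps, milling_order = mo)
}
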