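#' Log-likelihood of one observed swarm transition
#'
#' The transition probability of the observed new headings given the prior
#' state, a parameter set and a model variant. Because speed is constant
#' and positions are completely determined by headings, only heading
#' changes are scored. With `update_prob = 1` each particle contributes the
#' wrapped-Gaussian log density of (observed new heading - deterministic
#' predicted heading). With `update_prob = p < 1` the exact transition
#' density of the generative process is a two-component wrapped-Gaussian
#' mixture, `p * WG(new - predicted; sigma) + (1 - p) * WG(new - old;
#' sigma)`, since a non-updating particle keeps its old heading but is
#' still noised.
#'
#' @param state the prior single-timestep state tibble.
#' @param new_headings numeric vector of observed headings at the next
#'   timestep, ordered by particle id.
#' @param params a [model_params()] object; `noise_sd` must be positive.
#' @param spec a [model_spec()] object.
#' @param arena_size optional override of the state's arena size.
#' @return the summed log transition density over particles.
#' @export
step_loglik <- function(state, new_headings, params, spec = model_spec(),
                        arena_size = NULL) {
  st <- st_with_geom(state, arena_size)
  n <- length(st$x)
  if (length(new_headings) != n) {
    abort("`new_headings` must have one entry per particle in `state`.")
  }
  if (params$noise_sd <= 0) {
    abort("The likelihood needs `noise_sd` > 0.")
  }
  mask <- neighbour_mask(st$geom, spec$neighbourhood, params$blind_angle,
    radius = params$interaction_radius, k = params$neighbour_count
  )
  wa <- if (spec$attraction) params$attraction_weight else 0
  wl <- if (spec$alignment) params$alignment_weight else 0
  pred <- predicted_headings_all(st, mask, wa, wl)
  lw_update <- dwrapnorm(wrap_angle(new_headings - pred), params$noise_sd, log = TRUE)
  p <- params$update_prob
  if (p >= 1) {
    return(sum(lw_update))
  }
  lw_keep <- dwrapnorm(wrap_angle(new_headings - st$heading), params$noise_sd, log = TRUE)
  m <- pmax(lw_update, lw_keep)
  terms <- base::log(p * exp(lw_update - m) + (1 - p) * exp(lw_keep - m)) + m
  terms[m == -Inf] <- -Inf # both components underflowed
  sum(terms)
}

#' Log-likelihood of a trajectory
#'
#' Sum of [step_loglik()] over the consecutive state pairs of a trajectory.
#' The dynamics are Markovian, so the result is additive over disjoint
#' time blocks.
#'
#' @param traj a swarm trajectory tibble.
#' @param params a [model_params()] object.
#' @param spec a [model_spec()] object.
#' @param t_range optional `c(first, last)` timestep interval (inclusive)
#'   to score; defaults to the whole trajectory.
#' @param arena_size optional override of the trajectory's arena size.
#' @return the summed log transition density over particles and timesteps.
#' @export
trajectory_loglik <- function(traj, params, spec = model_spec(),
                              t_range = NULL, arena_size = NULL) {
  L <- arena_size_of(traj, arena_size)
  ts <- sort(unique(traj$t))
  if (is.null(t_range)) t_range <- range(ts)
  if (t_range[1] < min(ts) || t_range[2] > max(ts) || t_range[1] >= t_range[2]) {
    abort("`t_range` must be an interval of at least two timesteps inside the trajectory.")
  }
  use <- ts[ts >= t_range[1] & ts <= t_range[2]]
  total <- 0
  for (i in seq_len(length(use) - 1L)) {
    st <- state_at(traj, use[i])
    nxt <- state_at(traj, use[i + 1L])
    nh <- nxt$heading[order(nxt$particle)]
    total <- total + step_loglik(st, nh, params, spec, arena_size = L)
  }
  total
}
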