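#' Fresh posterior from a parameter grid
#'
#' Returns the prior as a posterior object with no data assimilated:
#' normalised log mass equal to the grid prior, zero assimilated steps and
#' zero cumulative log evidence.
#'
#' @param grid a [make_grid()] object.
#' @return an object of class `swarm_posterior`.
#' @export
posterior <- function(grid) {
  structure(
    list(
      grid = grid,
      log_mass = grid$log_prior - logsumexp(grid$log_prior),
      n_steps = 0L,
      log_evidence = 0
    ),
    class = "swarm_posterior"
  )
}

#' Sequential Bayesian update of a grid posterior
#'
#' Assimilates the consecutive transitions of a trajectory (or slice of
#' one): for every grid point the transition log-likelihood is added to
#' the current log mass, which is then renormalised. The log normalising
#' constant of each step accumulates into the cumulative log evidence
#' `log p(data | model)`, the quantity compared by [log_bayes_factor()].
#' Because the dynamics are Markovian and the grid is finite, assimilating
#' data in two batches is exactly equivalent to assimilating it in one.
#'
#' @param post a `swarm_posterior` (for a fresh prior use
#'   `posterior(make_grid(spec))`).
#' @param data a swarm trajectory tibble with at least two timesteps (an
#'   empty or single-timestep tibble leaves the posterior unchanged).
#' @param t_range optional `c(first, last)` timestep interval to
#'   assimilate.
#' @param arena_size optional override of the trajectory's arena size.
#' @return the updated `swarm_posterior`.
#' @export
#' @examples
#' params <- reference_params()
#' traj <- simulate_swarm(params, n_steps = 3, n_particles = 10, seed = 1)
#' post <- posterior(make_grid(reference_spec(), resolution = 4))
#' post <- update_posterior(post, traj)
#' glance(post)
update_posterior <- function(post, data, t_range = NULL, arena_size = NULL) {
  stopifnot(inherits(post, "swarm_posterior"))
  if (is.null(data) || nrow(data) == 0L) {
    return(post)
  }
  L <- arena_size_of(data, arena_size)
  ts <- sort(unique(data$t))
  if (!is.null(t_range)) {
    if (t_range[1] < min(ts) || t_range[2] > max(ts)) {
      abort("`t_range` lies outside the trajectory.")
    }
    ts <- ts[ts >= t_range[1] & ts <= t_range[2]]
  }
  if (length(ts) < 2L) {
    return(post)
  }
  df <- data[order(data$t, data$particle), ]
  log_mass <- post$log_mass
  log_evidence <- post$log_evidence
  for (i in seq_len(length(ts) - 1L)) {
    cur <- df[df$t == ts[i], ]
    nxt <- df[df$t == ts[i + 1L], ]
    st <- list(
      t = ts[i], x = cur$x, y = cur$y, heading = cur$heading, arena_size = L
    )
    st$geom <- pairwise_geometry(st$x, st$y, st$heading, L)
    log_mass <- log_mass + grid_step_loglik(st, nxt$heading, post$grid)
    z <- logsumexp(log_mass)
    log_evidence <- log_evidence + z
    log_mass <- log_mass - z
  }
  structure(
    list(
      grid = post$grid, log_mass = log_mass,
      n_steps = post$n_steps + length(ts) - 1L,
      log_evidence = log_evidence
    ),
    class = "swarm_posterior"
  )
}

## mass marginalised onto one or more axes (axis-value order; for several
## axes the first varies fastest, as in the full grid)
marginal_mass <- function(post, parameter) {
  axes <- post$grid$axes
  bad <- setdiff(parameter, names(axes))
  if (length(bad)) {
    abort(paste0("`", bad[1], "` is not an axis of this grid."))
  }
  dims <- vapply(axes, length, integer(1))
  arr <- array(exp(post$log_mass), dims)
  keep <- sort(match(parameter, names(axes)))
  as.numeric(apply(arr, keep, sum))
}

#' Marginal posterior over one parameter
#'
#' @param post a `swarm_posterior`.
#' @param parameter name of a grid axis.
#' @return a tibble with one row per axis value: columns `parameter`,
#'   `value`, `mass`.
#' @export
marginal <- function(post, parameter) {
  mass <- marginal_mass(post, parameter)
  tibble::tibble(
    parameter = parameter,
    value = post$grid$axes[[parameter]],
    mass = mass
  )
}

#' Mass-weighted mean and SD of each marginal
#'
#' The summary convention used throughout the experiment pipelines: each
#' parameter's marginal distribution is condensed to its mass-weighted
#' mean and standard deviation.
#'
#' @param post a `swarm_posterior`.
#' @param parameter one axis name, or `NULL` for all axes.
#' @return a tibble with columns `parameter`, `mean`, `sd`.
#' @export
marginal_summary <- function(post, parameter = NULL) {
  pars <- parameter %||% names(post$grid$axes)
  purrr::map_dfr(pars, function(nm) {
    m <- marginal(post, nm)
    mu <- sum(m$value * m$mass)
    tibble::tibble(
      parameter = nm, mean = mu,
      sd = sqrt(max(0, sum(m$mass * (m$value - mu)^2)))
    )
  })
}

#' Shannon entropy of a posterior
#'
#' Entropy of the joint grid distribution (or of one marginal), the
#' package's single-number summary of remaining parameter uncertainty: it
#' equals `log(grid size)` for the uniform prior and tends to 0 as the
#' distribution converges to a point.
#'
#' @param post a `swarm_posterior`.
#' @param parameter optional axis name (entropy of that marginal) or
#'   vector of axis names (entropy of their joint marginal, which makes
#'   posteriors over grids that differ only in the remaining axes
#'   comparable).
#' @param base logarithm base (natural log by default; use 2 for bits).
#' @return a non-negative scalar.
#' @export
posterior_entropy <- function(post, parameter = NULL, base = exp(1)) {
  if (is.null(parameter)) {
    lm <- post$log_mass
    h <- -sum(exp(lm) * lm, na.rm = TRUE)
  } else {
    m <- marginal_mass(post, parameter)
    m <- m[m > 0]
    h <- -sum(m * base::log(m))
  }
  max(0, h) / base::log(base)
}

#' Log Bayes factor between two fitted models
#'
#' The difference of the cumulative log evidences of two posteriors that
#' have assimilated the *same* observations; positive values favour the
#' first model. The parameters of each model are marginalised by the grid
#' sum inside the evidence, so the comparison carries the usual automatic
#' complexity (Occam) penalty. Additive across sequential data blocks.
#'
#' @param post1,post2 `swarm_posterior` objects fitted to identical data.
#' @return the log Bayes factor of model 1 over model 2.
#' @export
log_bayes_factor <- function(post1, post2) {
  stopifnot(inherits(post1, "swarm_posterior"), inherits(post2, "swarm_posterior"))
  if (post1$n_steps != post2$n_steps) {
    abort("Both models must have assimilated the same observations.")
  }
  post1$log_evidence - post2$log_evidence
}

## ---- tidiers and printing ------------------------------------------------

#' Tidy a posterior into a grid-point tibble
#'
#' @param x a `swarm_posterior`.
#' @param ... unused.
#' @return a tibble with one row per grid point: the parameter values,
#'   `log_mass` and `mass`.
#' @export
tidy.swarm_posterior <- function(x, ...) {
  out <- tibble::as_tibble(expand.grid(x$grid$axes, KEEP.OUT.ATTRS = FALSE))
  out$log_mass <- x$log_mass
  out$mass <- exp(x$log_mass)
  out
}

#' One-row posterior summary
#'
#' @param x a `swarm_posterior`.
#' @param ... unused.
#' @return a tibble with `n_grid`, `n_steps`, `entropy` (nats),
#'   `prior_entropy` and `log_evidence`.
#' @export
glance.swarm_posterior <- function(x, ...) {
  tibble::tibble(
    n_grid = grid_size(x$grid),
    n_steps = x$n_steps,
    entropy = posterior_entropy(x),
    prior_entropy = base::log(grid_size(x$grid)),
    log_evidence = x$log_evidence
  )
}

#' @export
print.swarm_posterior <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<swarm_posterior> %d grid points, %d steps assimilated\n  entropy %.3f / %.3f nats, log evidence %.3f\n",
    g$n_grid, g$n_steps, g$entropy, g$prior_entropy, g$log_evidence
  ))
  print(marginal_summary(x))
  invisible(x)
}
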