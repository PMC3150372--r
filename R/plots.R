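#' Plot a swarm state or trajectory
#'
#' Scatter of particle positions with heading arrows (one timestep). For a
#' full trajectory the last timestep is shown unless `t` is given.
#'
#' @param object a `swarm_trajectory` tibble.
#' @param t timestep to draw; defaults to the last.
#' @param arrow_length arrow length in arena units.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.swarm_trajectory <- function(object, t = max(object$t),
                                      arrow_length = 0.4, ...) {
  st <- state_at(object, t)
  L <- arena_size_of(st)
  ggplot2::ggplot(st, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_segment(
      ggplot2::aes(
        xend = .data$x + arrow_length * cos(.data$heading),
        yend = .data$y + arrow_length * sin(.data$heading)
      ),
      colour = "red",
      arrow = ggplot2::arrow(length = ggplot2::unit(0.12, "cm"))
    ) +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::coord_fixed(xlim = c(0, L), ylim = c(0, L), expand = FALSE) +
    ggplot2::labs(
      title = paste0("Swarm state at t = ", t),
      x = NULL, y = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot the marginal distributions of a posterior
#'
#' @param object a `swarm_posterior`.
#' @param ... unused.
#' @return a ggplot object with one panel per parameter axis.
#' @export
autoplot.swarm_posterior <- function(object, ...) {
  m <- purrr::map_dfr(names(object$grid$axes), function(nm) marginal(object, nm))
  ggplot2::ggplot(m, ggplot2::aes(x = .data$value, y = .data$mass)) +
    ggplot2::geom_col(width = NULL) +
    ggplot2::facet_wrap(~parameter, scales = "free_x") +
    ggplot2::labs(x = "parameter value", y = "posterior mass") +
    ggplot2::theme_minimal()
}

#' Plot a scenario report
#'
#' Draws the figure matching the scenario type: posterior mean with SD
#' ribbons against assimilated steps (convergence), against the true noise
#' level (noise sweep) or the true update rate (update-rate sweep), and
#' cumulative log Bayes factor against assimilated steps for model
#' selection. Seed-averaged records are shown.
#'
#' @param object a `scenario_report`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.scenario_report <- function(object, ...) {
  avg <- object$records[is.na(object$records$seed), ]
  if (object$scenario == "model_selection") {
    grp <- interaction(avg$generator, avg$arm)
    return(
      ggplot2::ggplot(avg, ggplot2::aes(
        x = .data$step, y = .data$log_bf,
        colour = .data$generator, linetype = .data$arm, group = grp
      )) +
        ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
        ggplot2::geom_line() +
        ggplot2::geom_point() +
        ggplot2::labs(
          x = "assimilated timesteps",
          y = "cumulative log Bayes factor (model 1 over model 2)"
        ) +
        ggplot2::theme_minimal()
    )
  }
  xvar <- switch(object$scenario,
    convergence = "step",
    noise_sweep = "sigma_true",
    update_rate_sweep = "p_true",
    "step"
  )
  aes_args <- ggplot2::aes(
    x = .data[[xvar]], y = .data$mean,
    ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd
  )
  p <- ggplot2::ggplot(avg, aes_args)
  if (object$scenario == "convergence") {
    p <- ggplot2::ggplot(avg, utils::modifyList(
      aes_args, ggplot2::aes(colour = .data$arm, fill = .data$arm)
    ))
  }
  p +
    ggplot2::geom_ribbon(alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = gsub("_", " ", xvar), y = "posterior mean ± SD") +
    ggplot2::theme_minimal()
}
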