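## Experiment pipelines: seeded, end-to-end study scenarios that pair the
## simulator with the grid posterior engine and return tidy reports.

new_scenario_report <- function(scenario, records, seeds, config,
                                excluded_seeds = integer(0)) {
  structure(
    list(
      scenario = scenario, records = records, seeds = seeds,
      excluded_seeds = excluded_seeds, config = config
    ),
    class = "scenario_report"
  )
}

#' @export
print.scenario_report <- function(x, ...) {
  cat("<scenario_report> ", x$scenario, ": ", nrow(x$records), " records, seeds ",
    paste(x$seeds, collapse = ","), "\n",
    sep = ""
  )
  if (length(x$excluded_seeds)) {
    cat("  excluded seeds (no steady state): ", paste(x$excluded_seeds, collapse = ","), "\n")
  }
  invisible(x)
}

#' Records of a scenario report
#'
#' @param x a `scenario_report`.
#' @param ... unused.
#' @return the tidy per-increment record tibble, including the
#'   seed-averaged rows (`seed` is `NA` there).
#' @export
tidy.scenario_report <- function(x, ...) {
  x$records
}

## long per-parameter summary rows for one fitted posterior
posterior_record <- function(post) {
  ms <- marginal_summary(post)
  ms$marginal_entropy <- vapply(
    ms$parameter, function(nm) posterior_entropy(post, nm), numeric(1)
  )
  ms$entropy <- posterior_entropy(post)
  ## entropy over the structural parameters only: when the update rate is a
  ## free axis this is the joint marginal with update_prob summed out, which
  ## is the comparable quantity across p-fixed and p-free fits
  shared <- setdiff(names(post$grid$axes), "update_prob")
  ms$entropy_shared <- if (length(shared) < length(post$grid$axes)) {
    posterior_entropy(post, shared)
  } else {
    ms$entropy[1]
  }
  ms$log_evidence <- post$log_evidence
  ms
}

## average the numeric summary columns over seeds
seed_average <- function(records, group_cols) {
  num_cols <- setdiff(
    names(records)[vapply(records, is.numeric, logical(1))],
    c(group_cols, "seed")
  )
  avg <- records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(num_cols), mean),
      .groups = "drop"
    )
  avg$seed <- NA_integer_
  dplyr::bind_rows(records, avg)
}

#' Convergence of inference with growing data
#'
#' For each seed, simulates a swarm from a random initial configuration
#' and assimilates its first `n_steps` transitions one at a time,
#' recording each parameter's posterior mean and SD, the per-parameter
#' marginal entropies and the joint entropy after every increment; then
#' burns the same system into the rotating-mill steady state and repeats
#' the incremental analysis on `n_steps` steady-state transitions. Seeds
#' whose swarm never reaches the mill within the burn-in horizon are
#' excluded from the steady-state arm with a warning and flagged in the
#' report.
#'
#' @param params_true the generating [model_params()].
#' @param spec the [model_spec()] used both to simulate and to infer.
#' @param n_seeds number of independent replicate simulations.
#' @param n_steps transitions assimilated per arm.
#' @param n_particles swarm size.
#' @param resolution grid resolution passed to [make_grid()].
#' @param burn_in list with `threshold`, `window`, `max_steps` for
#'   [steady_state_swarm()].
#' @param seeds explicit seed vector (overrides `n_seeds`).
#' @return a `scenario_report` whose records have one row per seed, arm
#'   (`"random"` or `"steady"`), assimilated-step count and parameter,
#'   plus seed-averaged rows.
#' @export
run_convergence_scenario <- function(params_true, spec = model_spec(),
                                     n_seeds = 5, n_steps = 10,
                                     n_particles = 25, resolution = 9,
                                     burn_in = list(threshold = 0.8, window = 10, max_steps = 3000),
                                     seeds = NULL) {
  stopifnot(n_steps >= 1)
  seeds <- seeds %||% seq_len(n_seeds)
  grid <- make_grid(spec, resolution)
  excluded <- integer(0)
  records <- purrr::map_dfr(seeds, function(seed) {
    traj <- simulate_swarm(params_true, n_steps, n_particles, spec, seed = seed)
    arms <- list(random = traj)
    ss <- steady_state_swarm(params_true, n_particles, spec,
      seed = seed + 10000L,
      threshold = burn_in$threshold, window = burn_in$window,
      max_steps = burn_in$max_steps
    )
    if (ss$reached) {
      arms$steady <- simulate_swarm(params_true, n_steps, n_particles, spec,
        init = ss$state
      )
    } else {
      warn(paste0("Seed ", seed, ": no steady-state mill within burn-in horizon; arm skipped."))
      excluded <<- c(excluded, seed)
    }
    purrr::map_dfr(names(arms), function(arm) {
      post <- posterior(grid)
      purrr::map_dfr(seq_len(n_steps), function(k) {
        post <<- update_posterior(post, arms[[arm]], t_range = c(k - 1, k))
        rec <- posterior_record(post)
        rec$seed <- seed
        rec$arm <- arm
        rec$step <- k
        rec
      })
    })
  })
  new_scenario_report(
    "convergence",
    seed_average(records, c("arm", "step", "parameter")),
    seeds,
    config = list(
      params = unclass(params_true), spec = unclass(spec),
      n_steps = n_steps, n_particles = n_particles,
      resolution = resolution, burn_in = burn_in
    ),
    excluded_seeds = excluded
  )
}

#' Effect of angular noise on inference
#'
#' For each noise level and seed, simulates `n_steps` transitions from a
#' random initial configuration with `noise_sd` set to that level and runs
#' a full inference, recording the posterior summaries and the joint
#' entropy. The default specification widens the noise prior to
#' `[0.05, 2 * pi]` so that heavy noise levels stay inside the grid.
#'
#' @inheritParams run_convergence_scenario
#' @param sigma_values noise SDs (radians) to sweep; all must lie within
#'   the spec's `noise_sd` bounds.
#' @export
run_noise_sweep <- function(params_true, sigma_values = NULL,
                            spec = model_spec(bounds = list(noise_sd = c(0.05, 2 * pi))),
                            n_seeds = 5, n_steps = 10, n_particles = 25,
                            resolution = 9, seeds = NULL) {
  grid <- make_grid(spec, resolution)
  sigma_values <- sigma_values %||% grid$axes$noise_sd[seq_len(min(6, resolution))]
  bb <- spec$parameter_axes$noise_sd
  if (any(sigma_values <= 0 | sigma_values < bb[1] | sigma_values > bb[2])) {
    abort("All `sigma_values` must be positive and within the noise_sd bounds.")
  }
  seeds <- seeds %||% seq_len(n_seeds)
  records <- purrr::map_dfr(sigma_values, function(sig) {
    p <- params_true
    p$noise_sd <- sig
    purrr::map_dfr(seeds, function(seed) {
      traj <- simulate_swarm(p, n_steps, n_particles, spec, seed = seed)
      post <- update_posterior(posterior(grid), traj)
      rec <- posterior_record(post)
      rec$seed <- seed
      rec$sigma_true <- sig
      rec
    })
  })
  new_scenario_report(
    "noise_sweep",
    seed_average(records, c("sigma_true", "parameter")),
    seeds,
    config = list(
      params = unclass(params_true), spec = unclass(spec),
      sigma_values = sigma_values, n_steps = n_steps,
      n_particles = n_particles, resolution = resolution
    )
  )
}

#' Effect of the data-collection rate on inference
#'
#' Simulates swarms whose particles only re-compute their heading with
#' probability `p_true` per timestep (non-updaters keep their heading,
#' plus noise) and infers the parameters either assuming an update
#' probability of one (`infer_p = FALSE`) or with the update probability
#' as an additional grid axis (`infer_p = TRUE`).
#'
#' @inheritParams run_convergence_scenario
#' @param p_values true update probabilities to sweep, each in (0, 1].
#' @param infer_p whether the inference frees the update-rate axis.
#' @param resolution grid resolution (the default is one notch coarser
#'   than elsewhere because the freed update-rate axis adds a dimension).
#' @export
run_update_rate_sweep <- function(params_true, p_values = c(0.5, 1),
                                  infer_p = FALSE, spec = NULL,
                                  n_seeds = 5, n_steps = 10,
                                  n_particles = 25, resolution = 7,
                                  seeds = NULL) {
  stopifnot(all(p_values > 0 & p_values <= 1))
  spec <- spec %||% model_spec(infer_update_rate = infer_p)
  grid <- make_grid(spec, resolution, fixed_update_prob = 1)
  seeds <- seeds %||% seq_len(n_seeds)
  records <- purrr::map_dfr(p_values, function(p_true) {
    p <- params_true
    p$update_prob <- p_true
    purrr::map_dfr(seeds, function(seed) {
      traj <- simulate_swarm(p, n_steps, n_particles, spec, seed = seed)
      post <- update_posterior(posterior(grid), traj)
      rec <- posterior_record(post)
      rec$seed <- seed
      rec$p_true <- p_true
      rec$infer_p <- infer_p
      rec
    })
  })
  new_scenario_report(
    "update_rate_sweep",
    seed_average(records, c("p_true", "parameter")),
    seeds,
    config = list(
      params = unclass(params_true), spec = unclass(spec),
      p_values = p_values, infer_p = infer_p, n_steps = n_steps,
      n_particles = n_particles, resolution = resolution
    )
  )
}

#' Bayes-factor model selection between two rule variants
#'
#' Simulates data from each of two model variants in turn and, for every
#' seed and assimilation step, records the cumulative log Bayes factor of
#' candidate 1 over candidate 2 (both candidates assimilate exactly the
#' same observations). Run for a random-initial-configuration arm and,
#' optionally, a steady-state rotating-mill arm.
#'
#' @inheritParams run_convergence_scenario
#' @param params_1,params_2 generating [model_params()] for the two
#'   variants (for example, `params_2` with `alignment_weight = 0` or with
#'   a `neighbour_count` instead of a radius).
#' @param spec_1,spec_2 the two candidate [model_spec()]s; they must share
#'   the `noise_sd` axis bounds.
#' @param labels length-2 character labels for the candidates.
#' @param arms which data regimes to run (`"random"`, `"steady"`).
#' @return a `scenario_report` whose records hold `log_bf` (candidate 1
#'   over candidate 2) per generator, arm, seed and step.
#' @export
run_model_selection <- function(params_1, params_2, spec_1, spec_2,
                                labels = c("model_1", "model_2"),
                                n_seeds = 5, n_steps = 10, n_particles = 25,
                                resolution = 9, arms = "random",
                                burn_in = list(threshold = 0.8, window = 10, max_steps = 3000),
                                seeds = NULL) {
  if (!identical(
    spec_1$parameter_axes$noise_sd,
    spec_2$parameter_axes$noise_sd
  )) {
    abort("The two candidate specs must share the `noise_sd` axis bounds.")
  }
  seeds <- seeds %||% seq_len(n_seeds)
  grids <- list(make_grid(spec_1, resolution), make_grid(spec_2, resolution))
  gens <- list(
    list(label = labels[1], params = params_1, spec = spec_1),
    list(label = labels[2], params = params_2, spec = spec_2)
  )
  excluded <- integer(0)
  records <- purrr::map_dfr(gens, function(gen) {
    purrr::map_dfr(seeds, function(seed) {
      traj <- simulate_swarm(gen$params, n_steps, n_particles, gen$spec, seed = seed)
      arm_data <- list()
      if ("random" %in% arms) arm_data$random <- traj
      if ("steady" %in% arms) {
        ss <- steady_state_swarm(gen$params, n_particles, gen$spec,
          seed = seed + 10000L,
          threshold = burn_in$threshold, window = burn_in$window,
          max_steps = burn_in$max_steps
        )
        if (ss$reached) {
          arm_data$steady <- simulate_swarm(gen$params, n_steps, n_particles,
            gen$spec,
            init = ss$state
          )
        } else {
          warn(paste0(
            "Seed ", seed, " (", gen$label,
            "): no steady-state mill within burn-in horizon; arm skipped."
          ))
          excluded <<- c(excluded, seed)
        }
      }
      purrr::map_dfr(names(arm_data), function(arm) {
        p1 <- posterior(grids[[1]])
        p2 <- posterior(grids[[2]])
        purrr::map_dfr(seq_len(n_steps), function(k) {
          p1 <<- update_posterior(p1, arm_data[[arm]], t_range = c(k - 1, k))
          p2 <<- update_posterior(p2, arm_data[[arm]], t_range = c(k - 1, k))
          tibble::tibble(
            generator = gen$label, seed = seed, arm = arm, step = k,
            log_bf = log_bayes_factor(p1, p2)
          )
        })
      })
    })
  })
  new_scenario_report(
    "model_selection",
    seed_average(records, c("generator", "arm", "step")),
    seeds,
    config = list(
      params_1 = unclass(params_1), params_2 = unclass(params_2),
      spec_1 = unclass(spec_1), spec_2 = unclass(spec_2),
      labels = labels, n_steps = n_steps, n_particles = n_particles,
      resolution = resolution, arms = arms, burn_in = burn_in
    )
  )
}

#' Write a scenario report to disk
#'
#' Writes `<scenario>_records.csv` (the tidy records) and
#' `<scenario>_config.json` (seeds plus the configuration snapshot needed
#' to re-run the scenario) into `dir`.
#'
#' @param report a `scenario_report`.
#' @param dir output directory (created if needed).
#' @return the record CSV path, invisibly.
#' @export
write_scenario_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, paste0(report$scenario, "_records.csv"))
  readr::write_csv(report$records, csv)
  jsonlite::write_json(
    list(
      scenario = report$scenario, seeds = report$seeds,
      excluded_seeds = report$excluded_seeds, config = report$config
    ),
    file.path(dir, paste0(report$scenario, "_config.json")),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )
  invisible(csv)
}
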