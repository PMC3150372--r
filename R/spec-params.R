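## Canonical ordering of inferable parameters; grids and posteriors list
## their axes in this order.
axis_order <- c(
  "attraction_weight", "alignment_weight", "interaction_radius",
  "neighbour_count", "blind_angle", "noise_sd", "update_prob"
)

## Broad default prior bounds per inferable parameter (uniform priors are
## placed over these unless overridden through `bounds`).
default_bounds <- list(
  attraction_weight  = c(0, 2),
  alignment_weight   = c(0, 1),
  interaction_radius = c(0.5, 4.5),
  neighbour_count    = c(1, 13),
  blind_angle        = c(0, pi),
  noise_sd           = c(0.05, 0.85),
  update_prob        = c(0.1, 1)
)

#' Define a swarm model variant
#'
#' A model specification fixes which social forces act (attraction towards
#' neighbours, alignment with neighbours), how the interaction neighbourhood
#' is defined (metric/geometric radius versus topological nearest-neighbour
#' count), whether the heading-update probability is a free parameter, and
#' the prior bounds of every free parameter. The free parameters are exactly
#' those implied by the flags: the weight of each active force, the
#' interaction radius (geometric) or neighbour count (topological), the
#' blind angle, the angular noise SD, and — when `infer_update_rate` is
#' `TRUE` — the update probability.
#'
#' @param neighbourhood `"geometric"` (all visible particles within
#'   `interaction_radius`) or `"topological"` (the `neighbour_count` nearest
#'   visible particles).
#' @param attraction,alignment logical; include the attraction /
#'   alignment force. At least one must be `TRUE`.
#' @param infer_update_rate logical; treat the per-step heading-update
#'   probability as a free parameter (otherwise it is fixed at the value
#'   carried by the parameter set, typically 1).
#' @param bounds named list overriding the default `c(lower, upper)` prior
#'   bounds of individual parameters.
#' @return an object of class `swarm_spec`.
#' @seealso [model_params()], [make_grid()]
#' @export
#' @examples
#' model_spec()
#' model_spec("topological", alignment = FALSE)
model_spec <- function(neighbourhood = c("geometric", "topological"),
                       attraction = TRUE,
                       alignment = TRUE,
                       infer_update_rate = FALSE,
                       bounds = NULL) {
  neighbourhood <- match.arg(neighbourhood)
  if (!attraction && !alignment) {
    abort("At least one of `attraction` and `alignment` must be TRUE.")
  }
  free <- c(
    if (attraction) "attraction_weight",
    if (alignment) "alignment_weight",
    if (neighbourhood == "geometric") "interaction_radius" else "neighbour_count",
    "blind_angle",
    "noise_sd",
    if (infer_update_rate) "update_prob"
  )
  free <- intersect(axis_order, free)
  b <- default_bounds[free]
  if (!is.null(bounds)) {
    unknown <- setdiff(names(bounds), free)
    if (length(unknown)) {
      abort(paste0(
        "`bounds` given for parameters that are not free in this model: ",
        paste(unknown, collapse = ", ")
      ))
    }
    b[names(bounds)] <- bounds
  }
  for (nm in names(b)) {
    bb <- b[[nm]]
    if (length(bb) != 2L || !is.numeric(bb) || bb[1] >= bb[2]) {
      abort(paste0("Bounds for `", nm, "` must be c(lower, upper) with lower < upper."))
    }
  }
  structure(
    list(
      neighbourhood = neighbourhood,
      attraction = attraction,
      alignment = alignment,
      infer_update_rate = infer_update_rate,
      parameter_axes = b
    ),
    class = "swarm_spec"
  )
}

#' @export
print.swarm_spec <- function(x, ...) {
  forces <- c(if (x$attraction) "attraction", if (x$alignment) "alignment")
  cat("<swarm_spec> ", x$neighbourhood, " neighbourhood; forces: ",
    paste(forces, collapse = " + "),
    if (x$infer_update_rate) "; update rate inferred" else "", "\n",
    sep = ""
  )
  for (nm in names(x$parameter_axes)) {
    bb <- x$parameter_axes[[nm]]
    cat(sprintf("  %-18s in [%g, %g]\n", nm, bb[1], bb[2]))
  }
  invisible(x)
}

#' Define a concrete swarm parameter set
#'
#' One point in parameter space: the values actually used to simulate a
#' swarm (and, for the fixed quantities `speed`, `arena_size` and a
#' non-inferred `update_prob`, the values assumed during inference).
#'
#' @param attraction_weight,alignment_weight non-negative force weights
#'   relative to an inertial weight of one.
#' @param interaction_radius metric interaction range (length units); used
#'   by geometric neighbourhoods. May be `NULL` for purely topological use.
#' @param neighbour_count number of nearest visible neighbours interacted
#'   with; used by topological neighbourhoods. May be `NULL`.
#' @param blind_angle total angular width (radians, in `[0, 2 * pi)`) of the
#'   rear blind sector within which other particles are invisible.
#' @param noise_sd SD (radians) of the wrapped-Gaussian angular noise added
#'   to every heading at every step.
#' @param speed constant displacement per timestep (length units).
#' @param update_prob probability in `[0, 1]` that a particle re-computes
#'   its heading from the interaction rules on a given step (non-updaters
#'   keep their heading, still subject to noise; 0 is the frozen-heading
#'   simulator limit, while inference grids keep the axis positive).
#' @param arena_size side of the square periodic arena (length units).
#' @return an object of class `swarm_params`.
#' @seealso [reference_params()] for the package's documented reference set.
#' @export
model_params <- function(attraction_weight,
                         alignment_weight = 0,
                         interaction_radius = NULL,
                         neighbour_count = NULL,
                         blind_angle = 0,
                         noise_sd = 0,
                         speed = 0.2,
                         update_prob = 1,
                         arena_size = 10) {
  p <- list(
    attraction_weight = attraction_weight,
    alignment_weight = alignment_weight,
    interaction_radius = interaction_radius,
    neighbour_count = neighbour_count,
    blind_angle = blind_angle,
    noise_sd = noise_sd,
    speed = speed,
    update_prob = update_prob,
    arena_size = arena_size
  )
  validate_params(p)
  structure(p, class = "swarm_params")
}

validate_params <- function(p) {
  chk <- function(cond, msg) if (!cond) abort(msg)
  num1 <- function(v) is.numeric(v) && length(v) == 1L && is.finite(v)
  chk(num1(p$attraction_weight) && p$attraction_weight >= 0,
      "`attraction_weight` must be a single non-negative number.")
  chk(num1(p$alignment_weight) && p$alignment_weight >= 0,
      "`alignment_weight` must be a single non-negative number.")
  chk(num1(p$arena_size) && p$arena_size > 0, "`arena_size` must be positive.")
  if (!is.null(p$interaction_radius)) {
    chk(num1(p$interaction_radius) && p$interaction_radius > 0,
        "`interaction_radius` must be positive.")
    chk(p$interaction_radius <= p$arena_size,
        "`interaction_radius` must not exceed `arena_size`.")
  }
  if (!is.null(p$neighbour_count)) {
    chk(num1(p$neighbour_count) && p$neighbour_count >= 1 &&
          p$neighbour_count == round(p$neighbour_count),
        "`neighbour_count` must be an integer >= 1.")
  }
  chk(num1(p$blind_angle) && p$blind_angle >= 0 && p$blind_angle < 2 * pi,
      "`blind_angle` must lie in [0, 2 * pi).")
  chk(num1(p$noise_sd) && p$noise_sd >= 0, "`noise_sd` must be non-negative.")
  chk(num1(p$speed) && p$speed > 0, "`speed` must be positive.")
  chk(num1(p$update_prob) && p$update_prob >= 0 && p$update_prob <= 1,
      "`update_prob` must lie in [0, 1].")
  invisible(p)
}

#' @export
print.swarm_params <- function(x, ...) {
  cat("<swarm_params>\n")
  for (nm in names(x)) {
    if (!is.null(x[[nm]])) cat(sprintf("  %-18s %g\n", nm, x[[nm]]))
  }
  invisible(x)
}

#' Reference swarm configuration
#'
#' Loads the package's documented reference configuration — a 25-particle
#' swarm whose parameters were chosen so that, from random initial
#' conditions, the group reliably converges to the rotating-mill steady
#' state. The values live in a shipped YAML file
#' (`system.file("extdata", "reference_config.yaml", package = "swarmbayes")`)
#' rather than in code, so a study can be re-run from its configuration
#' alone.
#'
#' @param path optional path to an alternative YAML configuration.
#' @return `reference_config()` returns the parsed configuration list;
#'   `reference_params()` and `reference_spec()` return the corresponding
#'   [model_params()] and [model_spec()] objects.
#' @export
reference_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "reference_config.yaml", package = "swarmbayes")
  }
  read_run_config(path)
}

#' @rdname reference_config
#' @export
reference_params <- function(path = NULL) {
  config_params(reference_config(path))
}

#' @rdname reference_config
#' @export
reference_spec <- function(path = NULL) {
  config_spec(reference_config(path))
}
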