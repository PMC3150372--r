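## ---- trajectory files ----------------------------------------------------
## Plain CSV, header `t,particle,x,y,heading`, one row per particle per
## timestep, metadata in commented `# key: value` lines before the header.

#' Write a trajectory to a plain CSV file
#'
#' Rows are ordered t-major / particle-minor and floats are serialised with
#' 17 significant digits, so a write is byte-deterministic and a
#' write/read round trip is exact. Metadata (`arena_size`, `seed`, the
#' generating parameters when known) goes into commented header lines.
#'
#' @param traj a `swarm_trajectory` tibble.
#' @param path output file path.
#' @param arena_size optional override of the trajectory's arena size.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, arena_size = NULL) {
  L <- arena_size_of(traj, arena_size)
  df <- traj[order(traj$t, traj$particle), c("t", "particle", "x", "y", "heading")]
  meta <- c(sprintf("# arena_size: %.17g", L))
  seed <- attr(traj, "seed", exact = TRUE)
  if (!is.null(seed)) meta <- c(meta, sprintf("# seed: %d", as.integer(seed)))
  params <- attr(traj, "params", exact = TRUE)
  if (!is.null(params)) {
    meta <- c(meta, paste0(
      "# params: ",
      jsonlite::toJSON(params[!vapply(params, is.null, logical(1))],
        auto_unbox = TRUE, digits = NA
      )
    ))
  }
  rows <- sprintf(
    "%d,%d,%.17g,%.17g,%.17g",
    as.integer(df$t), as.integer(df$particle), df$x, df$y, df$heading
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(meta, "t,particle,x,y,heading", rows), con, sep = "\n")
  invisible(path)
}

#' Read a trajectory from a plain CSV file
#'
#' Expects the format written by [write_trajectory()]: commented metadata
#' lines, a `t,particle,x,y,heading` header, one row per particle per
#' timestep. Validates that timesteps are contiguous, that every timestep
#' contains the same particle set, and that positions lie inside the
#' periodic box; the first offending data row is named in the error.
#' Headings are wrapped to (-pi, pi] on read.
#'
#' @param path input file path.
#' @param arena_size optional override; by default taken from the file
#'   metadata (required if absent there).
#' @return a `swarm_trajectory` tibble.
#' @export
read_trajectory <- function(path, arena_size = NULL) {
  if (!file.exists(path)) abort(paste0("No such trajectory file: ", path))
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    m <- regmatches(ml, regexec("^#\\s*([a-zA-Z_]+):\\s*(.*)$", ml))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- m[3]
  }
  body <- lines[!grepl("^#", lines)]
  if (length(body) < 2L || trimws(body[1]) != "t,particle,x,y,heading") {
    abort("Trajectory file must start with the header `t,particle,x,y,heading`.")
  }
  ## base parser: strtod is correctly rounded, so 17-digit round trips are
  ## bit exact
  df <- tibble::as_tibble(utils::read.csv(
    text = paste(body, collapse = "\n"),
    colClasses = c(
      t = "integer", particle = "integer",
      x = "numeric", y = "numeric", heading = "numeric"
    )
  ))
  if (is.null(arena_size)) {
    if (is.null(meta$arena_size)) {
      abort("Trajectory file carries no `# arena_size:` metadata; pass `arena_size`.")
    }
    arena_size <- as.numeric(meta$arena_size)
  }
  df$.row <- seq_len(nrow(df))
  ts <- sort(unique(df$t))
  if (length(ts) && !all(diff(ts) == 1L)) {
    gap <- ts[which(diff(ts) != 1L)[1] + 1L]
    abort(paste0("Non-contiguous timesteps: t jumps to ", gap, "."))
  }
  ids <- sort(unique(df$particle[df$t == ts[1]]))
  for (tt in ts) {
    here <- sort(df$particle[df$t == tt])
    if (!identical(here, ids)) {
      missing_ids <- setdiff(ids, here)
      extra <- setdiff(here, ids)
      bad <- if (length(extra)) {
        df$.row[df$t == tt & df$particle == extra[1]][1]
      } else {
        max(df$.row[df$t == tt])
      }
      abort(paste0(
        "Inconsistent particle set at t=", tt, " (data row ", bad, "): ",
        if (length(missing_ids)) paste0("missing particle ", missing_ids[1]) else
          paste0("unexpected particle ", extra[1]), "."
      ))
    }
  }
  out_of_box <- which(df$x < 0 | df$x >= arena_size | df$y < 0 | df$y >= arena_size)
  if (length(out_of_box)) {
    abort(paste0(
      "Position outside [0, arena_size) at data row ", df$.row[out_of_box[1]], "."
    ))
  }
  df$heading <- wrap_angle(df$heading)
  df <- df[order(df$t, df$particle), c("t", "particle", "x", "y", "heading")]
  params <- NULL
  if (!is.null(meta$params)) {
    pl <- jsonlite::fromJSON(meta$params)
    params <- try(do.call(model_params, pl), silent = TRUE)
    if (inherits(params, "try-error")) params <- NULL
  }
  new_swarm_trajectory(df,
    arena_size = arena_size, params = params,
    seed = if (!is.null(meta$seed)) as.integer(meta$seed) else NULL
  )
}

## ---- run configuration ---------------------------------------------------

config_schema <- list(
  schema_version = NULL,
  model = c(
    "neighbourhood", "attraction", "alignment", "infer_update_rate", "bounds"
  ),
  params = c(
    "attraction_weight", "alignment_weight", "interaction_radius",
    "neighbour_count", "blind_angle", "noise_sd", "speed", "update_prob",
    "arena_size"
  ),
  run = c(
    "n_particles", "n_steps", "seeds", "resolution", "burn_in", "out_dir"
  )
)

validate_config <- function(cfg, source = "config") {
  unknown_top <- setdiff(names(cfg), names(config_schema))
  if (length(unknown_top)) {
    abort(paste0(source, ": unknown key `", unknown_top[1], "`."))
  }
  required <- c("schema_version", "model", "params", "run")
  for (key in required) {
    if (is.null(cfg[[key]])) abort(paste0(source, ": missing required key `", key, "`."))
  }
  for (blk in c("model", "params", "run")) {
    unknown <- setdiff(names(cfg[[blk]]), config_schema[[blk]])
    if (length(unknown)) {
      abort(paste0(source, ": unknown key `", blk, ".", unknown[1], "`."))
    }
  }
  for (key in c("n_particles", "n_steps", "seeds")) {
    if (is.null(cfg$run[[key]])) {
      abort(paste0(source, ": missing required key `run.", key, "`."))
    }
  }
  if (!is.null(cfg$run$burn_in)) {
    unknown <- setdiff(names(cfg$run$burn_in), c("threshold", "window", "max_steps"))
    if (length(unknown)) {
      abort(paste0(source, ": unknown key `run.burn_in.", unknown[1], "`."))
    }
  }
  invisible(cfg)
}

#' Read and write run configurations
#'
#' A run configuration is a YAML file with blocks `model` (a
#' [model_spec()] mirror), `params` (a [model_params()] mirror), and `run`
#' (`n_particles`, `n_steps`, `seeds`, optional `resolution`, `burn_in`,
#' `out_dir`), plus a `schema_version`. Unknown keys are rejected and
#' missing required keys are reported with their full path; parse →
#' serialise → parse is the identity.
#'
#' @param path file path.
#' @param cfg a configuration list as returned by `read_run_config()`.
#' @return `read_run_config()` returns the validated configuration list;
#'   `write_run_config()` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("No such config file: ", path))
  cfg <- yaml::read_yaml(path)
  validate_config(cfg, source = path)
  cfg
}

#' @rdname read_run_config
#' @export
write_run_config <- function(cfg, path) {
  validate_config(cfg)
  yaml::write_yaml(cfg, path, precision = 17)
  invisible(path)
}

## configuration block -> package objects
config_spec <- function(cfg) {
  m <- cfg$model
  model_spec(
    neighbourhood = m$neighbourhood %||% "geometric",
    attraction = m$attraction %||% TRUE,
    alignment = m$alignment %||% TRUE,
    infer_update_rate = m$infer_update_rate %||% FALSE,
    bounds = if (!is.null(m$bounds)) lapply(m$bounds, as.numeric) else NULL
  )
}

config_params <- function(cfg) {
  do.call(model_params, cfg$params)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
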