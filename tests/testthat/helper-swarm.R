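## Shared fixture builders; everything is generated in code.

## hand-built single state with explicit arena metadata
make_state <- function(x, y, heading, arena_size = 10, t = 0L) {
  st <- tibble::tibble(
    t = t, particle = seq_along(x), x = x, y = y, heading = heading
  )
  attr(st, "arena_size") <- arena_size
  st
}

## reference configuration objects
ref_params <- function() reference_params()
ref_spec <- function() reference_spec()

## a small params set for cheap tests
toy_params <- function(...) {
  modifyList(
    model_params(
      attraction_weight = 1, alignment_weight = 0.5,
      interaction_radius = 3, neighbour_count = 3,
      blind_angle = pi / 2, noise_sd = 0.2, speed = 0.2, arena_size = 10
    ),
    list(...)
  )
}

## brute-force neighbourhood predicate: tests every candidate particle
## independently against the visibility and distance/count rules
brute_neighbourhood <- function(st, fi, params, scheme, arena_size) {
  n <- nrow(st)
  keep <- integer(0)
  d <- rep(NA_real_, n)
  for (j in seq_len(n)) {
    if (j == fi) next
    dx <- st$x[j] - st$x[fi]
    dy <- st$y[j] - st$y[fi]
    dx <- dx - arena_size * floor(dx / arena_size + 0.5)
    dy <- dy - arena_size * floor(dy / arena_size + 0.5)
    d[j] <- sqrt(dx^2 + dy^2)
    bearing <- atan2(dy, dx) - st$heading[fi]
    bearing <- atan2(sin(bearing), cos(bearing))
    visible <- abs(bearing) <= pi - params$blind_angle / 2
    if (!visible) next
    if (scheme == "geometric") {
      if (d[j] <= params$interaction_radius) keep <- c(keep, j)
    } else {
      keep <- c(keep, j)
    }
  }
  if (scheme == "topological" && length(keep) > params$neighbour_count) {
    keep <- keep[order(d[keep], keep)][seq_len(params$neighbour_count)]
  }
  sort(keep)
}
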