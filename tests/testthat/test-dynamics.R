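test_that("neighbourhood obeys distance, count and blind-angle rules", {
  # full vision, everyone in range -> all N-1 others
  st <- make_state(
    x = c(5, 5.5, 4.5, 5), y = c(5, 5, 5, 5.6),
    heading = rep(0, 4)
  )
  p <- toy_params(blind_angle = 0)
  expect_setequal(neighbourhood(st, 1, p), c(2, 3, 4))

  # a particle exactly behind is blind for any positive blind angle
  st2 <- make_state(x = c(5, 4), y = c(5, 5), heading = c(0, 0))
  expect_length(neighbourhood(st2, 1, toy_params(blind_angle = pi / 2)), 0)

  # blind angle makes the relation directed: 1 sees 2 but not vice versa
  st3 <- make_state(x = c(5, 6), y = c(5, 5), heading = c(0, 0))
  p3 <- toy_params(blind_angle = pi / 2)
  expect_equal(neighbourhood(st3, 1, p3), 2)
  expect_length(neighbourhood(st3, 2, p3), 0)
})

test_that("neighbourhood matches a brute-force predicate filter", {
  set.seed(41)
  for (case in 1:20) {
    st <- make_state(
      x = runif(8, 0, 10), y = runif(8, 0, 10),
      heading = runif(8, -pi, pi), arena_size = 10
    )
    p <- toy_params(
      blind_angle = runif(1, 0, 1.9 * pi),
      interaction_radius = runif(1, 0.5, 8),
      neighbour_count = sample(1:7, 1)
    )
    for (scheme in c("geometric", "topological")) {
      spec <- model_spec(scheme)
      for (fi in c(1, 5, 8)) {
        expect_equal(
          sort(neighbourhood(st, fi, p, spec)),
          brute_neighbourhood(st, fi, p, scheme, 10)
        )
      }
    }
  }
})

test_that("social vectors follow the normalised-sum definitions", {
  st <- make_state(x = c(5, 6, 5), y = c(5, 5, 6), heading = c(0, 0, pi / 2))
  # single neighbour heading 0 -> alignment (1, 0)
  sv <- social_vectors(st, 1, 2)
  expect_equal(sv$alignment, c(1, 0))
  # centre of mass of (6,5) and (5,6) seen from (5,5) -> diagonal unit vector
  sv2 <- social_vectors(st, 1, c(2, 3))
  expect_equal(sv2$attraction, c(sqrt(2) / 2, sqrt(2) / 2), tolerance = 1e-12)

  # symmetric headings cancel: alignment undefined (NULL)
  st3 <- make_state(
    x = c(5, 6, 6), y = c(5, 5.5, 4.5),
    heading = c(0, pi / 2, -pi / 2)
  )
  sv3 <- social_vectors(st3, 1, c(2, 3))
  expect_null(sv3$alignment)
  expect_equal(sv3$attraction, c(1, 0), tolerance = 1e-12)

  expect_error(social_vectors(st, 1, c(1, 2)), "focal")
})

test_that("predicted direction is the normalised force sum", {
  # no neighbours -> inertia only
  st <- make_state(x = c(1, 9), y = c(1, 9), heading = c(0.3, -2))
  p <- toy_params(interaction_radius = 0.5)
  expect_equal(predicted_direction(st, 1, p), 0.3)
  expect_equal(predicted_direction(st, 2, p), -2)

  # overwhelming attraction turns straight at the neighbour (90 deg left)
  st2 <- make_state(x = c(5, 5), y = c(5, 6), heading = c(0, 0))
  p2 <- toy_params(attraction_weight = 1e9, alignment_weight = 0, blind_angle = 0)
  expect_equal(predicted_direction(st2, 1, p2), pi / 2, tolerance = 1e-6)

  # three particles, hand-evaluated vector sum
  st3 <- make_state(
    x = c(2, 3, 2), y = c(2, 2, 3),
    heading = c(0, pi / 2, pi)
  )
  p3 <- toy_params(
    attraction_weight = 1, alignment_weight = 0.5,
    interaction_radius = 3, blind_angle = 0
  )
  a_hat <- c(cos(pi / 2) + cos(pi), sin(pi / 2) + sin(pi))
  a_hat <- a_hat / sqrt(sum(a_hat^2))
  c_hat <- c(0.5, 0.5) / sqrt(0.5)
  v <- c(1, 0) + 0.5 * a_hat + 1 * c_hat
  expect_equal(predicted_direction(st3, 1, p3), atan2(v[2], v[1]), tolerance = 1e-12)
})

test_that("stepping has the correct ballistic and frozen limits", {
  st <- make_state(
    x = c(1, 5, 9), y = c(2, 5, 8), heading = c(0.5, -1, 3)
  )
  # no interactions, no noise, always update: straight-line motion
  p <- toy_params(interaction_radius = 0.1, noise_sd = 0, update_prob = 1)
  nxt <- step_swarm(st, p)
  expect_equal(nxt$heading, st$heading)
  expect_equal(nxt$x, (st$x + p$speed * cos(st$heading)) %% 10)
  expect_equal(nxt$y, (st$y + p$speed * sin(st$heading)) %% 10)
  expect_equal(unique(nxt$t), 1L)

  # never update, no noise: headings frozen, rigid translation
  p0 <- toy_params(interaction_radius = 5, noise_sd = 0, update_prob = 0, blind_angle = 0)
  nxt0 <- step_swarm(st, p0)
  expect_equal(nxt0$heading, st$heading)
  expect_equal(nxt0$x, (st$x + p0$speed * cos(st$heading)) %% 10)
})

test_that("deterministic update matches an independent reimplementation", {
  set.seed(51)
  st <- make_state(
    x = runif(5, 0, 10), y = runif(5, 0, 10), heading = runif(5, -pi, pi)
  )
  p <- toy_params(noise_sd = 0, update_prob = 1)
  got <- step_swarm(st, p)
  for (i in 1:5) {
    nb <- brute_neighbourhood(st, i, p, "geometric", 10)
    v <- c(cos(st$heading[i]), sin(st$heading[i]))
    if (length(nb)) {
      a <- c(sum(cos(st$heading[nb])), sum(sin(st$heading[nb])))
      if (sqrt(sum(a^2)) > 1e-12) v <- v + p$alignment_weight * a / sqrt(sum(a^2))
      dx <- st$x[nb] - st$x[i]
      dy <- st$y[nb] - st$y[i]
      dx <- dx - 10 * floor(dx / 10 + 0.5)
      dy <- dy - 10 * floor(dy / 10 + 0.5)
      cm <- c(mean(dx), mean(dy))
      if (sqrt(sum(cm^2)) > 1e-12) v <- v + p$attraction_weight * cm / sqrt(sum(cm^2))
    }
    expect_equal(got$heading[i], atan2(v[2], v[1]), tolerance = 1e-12)
    expect_equal(got$x[i], (st$x[i] + p$speed * cos(got$heading[i])) %% 10)
  }
})

test_that("milling order scores tangential, radial and random motion", {
  ang <- seq(0, 2 * pi, length.out = 9)[-9]
  cx <- 5 + 2 * cos(ang)
  cy <- 5 + 2 * sin(ang)
  sense <- rep(c(1, -1), 4) # mixed rotation senses still count as milling
  tangential <- make_state(cx, cy, wrap_angle(ang + sense * pi / 2))
  expect_equal(milling_order(tangential), 1)
  radial <- make_state(cx, cy, wrap_angle(ang))
  expect_equal(milling_order(radial), 0, tolerance = 1e-12)

  set.seed(61)
  random <- make_state(
    x = runif(4000, 4, 6), y = runif(4000, 4, 6),
    heading = runif(4000, -pi, pi)
  )
  expect_equal(milling_order(random), 2 / pi, tolerance = 0.03)
  expect_error(milling_order(make_state(5, 5, 0)), "at least 2")
})
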