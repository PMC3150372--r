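test_that("step log-likelihood equals an independent per-particle product", {
  st <- make_state(
    x = c(2, 3, 2), y = c(2, 2, 3), heading = c(0, pi / 2, pi)
  )
  p <- toy_params(noise_sd = 0.3, blind_angle = pi / 3)
  new_h <- c(0.4, 1.2, -3.0)
  # oracle: per-particle predicted heading from the public building blocks,
  # then an explicitly summed wrapped-Gaussian density
  wg <- function(d, s) {
    d <- atan2(sin(d), cos(d))
    sum(dnorm(d + 2 * pi * (-5:5), 0, s))
  }
  oracle <- 0
  for (i in 1:3) {
    pred <- predicted_direction(st, i, p)
    oracle <- oracle + log(wg(new_h[i] - pred, p$noise_sd))
  }
  expect_equal(step_loglik(st, new_h, p), oracle, tolerance = 1e-12)

  # small-noise peak: observing exactly the prediction gives N log(1/(s*sqrt(2*pi)))
  s_small <- 0.02
  p2 <- toy_params(noise_sd = s_small)
  pred_all <- vapply(1:3, function(i) predicted_direction(st, i, p2), numeric(1))
  expect_equal(
    step_loglik(st, pred_all, p2),
    3 * log(1 / (s_small * sqrt(2 * pi))),
    tolerance = 1e-9
  )

  expect_error(step_loglik(st, new_h[1:2], p), "per particle")
  expect_error(step_loglik(st, new_h, toy_params(noise_sd = 0)), "noise_sd")
})

test_that("the update-rate mixture degenerates correctly and normalises", {
  st <- make_state(
    x = c(2, 3, 2), y = c(2, 2, 3), heading = c(0, pi / 2, pi)
  )
  new_h <- c(0.4, 1.2, -3.0)
  p1 <- toy_params(noise_sd = 0.3, update_prob = 1)
  # with p = 1 the mixture collapses onto the pure update density
  expect_equal(
    step_loglik(st, new_h, p1),
    step_loglik(st, new_h, modifyList(p1, list(update_prob = 1 - 1e-15))),
    tolerance = 1e-9
  )

  # the per-particle transition density integrates to 1 for pure and mixture
  one <- make_state(x = 5, y = 5, heading = 0.7)
  for (pars in list(
    toy_params(noise_sd = 0.3), toy_params(noise_sd = 1.5),
    toy_params(noise_sd = 0.3, update_prob = 0.6),
    toy_params(noise_sd = 2.5, update_prob = 0.25)
  )) {
    dens <- function(h) {
      vapply(h, function(hh) exp(step_loglik(one, hh, pars)), numeric(1))
    }
    q <- integrate(dens, -pi, pi, rel.tol = 1e-9, subdivisions = 400)
    expect_equal(q$value, 1, tolerance = 1e-6)
  }
})

test_that("trajectory log-likelihood is Markov-additive over time blocks", {
  p <- ref_params()
  traj <- simulate_swarm(p, n_steps = 10, n_particles = 8, seed = 71)
  full <- trajectory_loglik(traj, p)
  expect_equal(
    full,
    trajectory_loglik(traj, p, t_range = c(0, 5)) +
      trajectory_loglik(traj, p, t_range = c(5, 10)),
    tolerance = 1e-10
  )
  # a single transition reproduces step_loglik exactly
  st0 <- state_at(traj, 3)
  st1 <- state_at(traj, 4)
  expect_equal(
    trajectory_loglik(traj, p, t_range = c(3, 4)),
    step_loglik(st0, st1$heading[order(st1$particle)], p)
  )
  expect_error(trajectory_loglik(traj, p, t_range = c(0, 99)), "t_range")
})

test_that("likelihood is invariant to rigid translation of the swarm", {
  p <- ref_params()
  traj <- simulate_swarm(p, n_steps = 3, n_particles = 10, seed = 72)
  shifted <- traj
  shifted$x <- (shifted$x + 3.7) %% 10
  shifted$y <- (shifted$y + 8.1) %% 10
  attr(shifted, "arena_size") <- 10
  expect_equal(
    trajectory_loglik(traj, p),
    trajectory_loglik(shifted, p, arena_size = 10),
    tolerance = 1e-9
  )
})

test_that("likelihood is invariant to rigid rotation of an interior cluster", {
  # a compact cluster far from the boundary, rotated 90 degrees about the
  # box centre: neighbourhoods and geometry are preserved exactly
  set.seed(73)
  x <- runif(8, 4.2, 5.8)
  y <- runif(8, 4.2, 5.8)
  h <- runif(8, -pi, pi)
  st <- make_state(x, y, h)
  new_h <- wrap_angle(h + rnorm(8, 0, 0.2))
  rot <- function(px, py) list(x = 5 - (py - 5), y = 5 + (px - 5))
  r <- rot(x, y)
  st_r <- make_state(r$x, r$y, wrap_angle(h + pi / 2))
  p <- toy_params(noise_sd = 0.4)
  expect_equal(
    step_loglik(st, new_h, p),
    step_loglik(st_r, wrap_angle(new_h + pi / 2), p),
    tolerance = 1e-9
  )
})

test_that("the generating parameters beat distant parameters on average", {
  p <- ref_params()
  p_far <- modifyList(p, list(
    attraction_weight = 0.25, alignment_weight = 0.75, noise_sd = 0.5
  ))
  diffs <- vapply(1:4, function(seed) {
    traj <- simulate_swarm(p, n_steps = 5, n_particles = 15, seed = 80 + seed)
    trajectory_loglik(traj, p) - trajectory_loglik(traj, p_far)
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})
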