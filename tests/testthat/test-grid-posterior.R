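test_that("grids honour bounds, resolutions and the uniform prior", {
  spec <- model_spec()
  g <- make_grid(spec, resolution = 3)
  expect_equal(grid_size(g), 3^5)
  expect_equal(sum(exp(g$log_prior)), 1, tolerance = 1e-10)
  for (nm in names(spec$parameter_axes)) {
    expect_equal(range(g$axes[[nm]]), spec$parameter_axes[[nm]])
  }
  # fresh prior is uniform, so its entropy is log(grid size)
  expect_equal(posterior_entropy(posterior(g)), log(3^5), tolerance = 1e-10)
  expect_error(make_grid(spec, resolution = 1), "at least 2")
  expect_error(make_grid(spec, resolution = c(bogus = 3)), "not free")

  pts <- tidy(g)
  expect_equal(nrow(pts), 3^5)
  expect_equal(sort(unique(pts$attraction_weight)), g$axes$attraction_weight)
})

test_that("sequential updating equals batch updating exactly", {
  p <- ref_params()
  traj <- simulate_swarm(p, n_steps = 6, n_particles = 10, seed = 91)
  g <- make_grid(ref_spec(), resolution = 3)
  batch <- update_posterior(posterior(g), traj)
  seq_post <- posterior(g)
  for (k in 1:6) {
    seq_post <- update_posterior(seq_post, traj, t_range = c(k - 1, k))
  }
  expect_equal(seq_post$log_mass, batch$log_mass, tolerance = 1e-10)
  expect_equal(seq_post$log_evidence, batch$log_evidence, tolerance = 1e-10)
  expect_equal(seq_post$n_steps, batch$n_steps)

  two_blocks <- update_posterior(
    update_posterior(posterior(g), traj, t_range = c(0, 3)),
    traj,
    t_range = c(3, 6)
  )
  expect_equal(two_blocks$log_mass, batch$log_mass, tolerance = 1e-10)

  # assimilating nothing is the identity
  same <- update_posterior(batch, traj[0, ])
  expect_identical(same$log_mass, batch$log_mass)
  expect_identical(same$n_steps, batch$n_steps)
})

test_that("grid posterior matches a naive per-point enumeration oracle", {
  p <- ref_params()
  traj <- simulate_swarm(p, n_steps = 2, n_particles = 6, seed = 92)
  spec <- model_spec(alignment = FALSE)
  g <- make_grid(spec, resolution = 2) # 16 points
  post <- update_posterior(posterior(g), traj)

  pts <- tidy(g)
  ll <- vapply(seq_len(nrow(pts)), function(i) {
    pars <- model_params(
      attraction_weight = pts$attraction_weight[i],
      interaction_radius = pts$interaction_radius[i],
      blind_angle = pts$blind_angle[i],
      noise_sd = pts$noise_sd[i],
      speed = p$speed, arena_size = p$arena_size
    )
    trajectory_loglik(traj, pars, spec)
  }, numeric(1))
  unnorm <- g$log_prior + ll
  z <- max(unnorm) + log(sum(exp(unnorm - max(unnorm))))
  expect_equal(post$log_mass, unnorm - z, tolerance = 1e-10)
  expect_equal(post$log_evidence, z, tolerance = 1e-10)
})

test_that("a two-point noise axis reproduces the two-hypothesis Bayes rule", {
  # single particle, no interactions: the transition density depends only
  # on the noise SD, so the posterior odds between the two sigma values
  # must equal the hand-computed likelihood ratio (uniform prior)
  one <- simulate_swarm(
    model_params(
      attraction_weight = 1, interaction_radius = 1,
      noise_sd = 0.3, speed = 0.2, arena_size = 10
    ),
    n_steps = 1, n_particles = 1, seed = 93
  )
  spec <- model_spec(bounds = list(noise_sd = c(0.2, 0.6)))
  g <- make_grid(spec, resolution = 2)
  post <- update_posterior(posterior(g), one)
  m <- marginal(post, "noise_sd")

  h0 <- state_at(one, 0)$heading
  h1 <- state_at(one, 1)$heading
  lr <- dwrapnorm(h1 - h0, 0.2) / dwrapnorm(h1 - h0, 0.6)
  expect_equal(m$mass[1] / m$mass[2], lr, tolerance = 1e-9)
})

test_that("marginals and their moments match a brute-force double loop", {
  g <- make_grid(model_spec(alignment = FALSE), resolution = c(
    attraction_weight = 3, interaction_radius = 4,
    blind_angle = 2, noise_sd = 2
  ))
  post <- posterior(g)
  set.seed(94)
  w <- runif(grid_size(g))
  post$log_mass <- log(w / sum(w))

  pts <- tidy(post)
  for (nm in names(g$axes)) {
    m <- marginal(post, nm)
    brute <- vapply(
      g$axes[[nm]],
      function(v) sum(pts$mass[pts[[nm]] == v]),
      numeric(1)
    )
    expect_equal(m$mass, brute, tolerance = 1e-12)
    ms <- marginal_summary(post, nm)
    expect_equal(ms$mean, sum(g$axes[[nm]] * brute), tolerance = 1e-12)
    expect_equal(
      ms$sd,
      sqrt(sum(brute * (g$axes[[nm]] - ms$mean)^2)),
      tolerance = 1e-12
    )
  }
  expect_error(marginal(post, "no_such_axis"), "not an axis")
})

test_that("entropy has the uniform, point-mass and mixed reference values", {
  g <- make_grid(model_spec(), resolution = 2) # 32 points
  post <- posterior(g)
  expect_equal(posterior_entropy(post), log(32), tolerance = 1e-12)
  expect_equal(posterior_entropy(post, base = 2), 5, tolerance = 1e-12)

  point <- post
  point$log_mass <- c(0, rep(-Inf, 31))
  expect_equal(posterior_entropy(point), 0)

  mixed <- post
  mixed$log_mass <- log(c(0.5, 0.25, 0.25, rep(0, 29)))
  expect_equal(posterior_entropy(mixed, base = 2), 1.5, tolerance = 1e-12)

  # uniform posterior on a symmetric axis: mean at the midpoint, and a
  # point mass has zero SD
  ms <- marginal_summary(post, "blind_angle")
  expect_equal(ms$mean, pi / 2, tolerance = 1e-12)
  expect_equal(marginal_summary(point, "attraction_weight")$sd, 0)
})

test_that("Bayes factors are zero for identical models and additive in data", {
  p <- ref_params()
  traj <- simulate_swarm(p, n_steps = 4, n_particles = 8, seed = 95)
  g <- make_grid(ref_spec(), resolution = 3)
  pa <- update_posterior(posterior(g), traj)
  pb <- update_posterior(posterior(g), traj)
  expect_equal(log_bayes_factor(pa, pb), 0)

  g2 <- make_grid(model_spec(alignment = FALSE), resolution = 3)
  full_a <- update_posterior(posterior(g), traj)
  full_b <- update_posterior(posterior(g2), traj)
  bf_full <- log_bayes_factor(full_a, full_b)

  a1 <- update_posterior(posterior(g), traj, t_range = c(0, 2))
  b1 <- update_posterior(posterior(g2), traj, t_range = c(0, 2))
  a2 <- update_posterior(a1, traj, t_range = c(2, 4))
  b2 <- update_posterior(b1, traj, t_range = c(2, 4))
  expect_equal(
    bf_full,
    log_bayes_factor(a1, b1) +
      (log_bayes_factor(a2, b2) - log_bayes_factor(a1, b1)),
    tolerance = 1e-10
  )
  expect_equal(log_bayes_factor(a2, b2), bf_full, tolerance = 1e-10)

  # mismatched data loads are rejected
  expect_error(log_bayes_factor(a1, b2), "same observations")
})

test_that("a two-model toy comparison matches a hand-summed evidence ratio", {
  p <- ref_params()
  traj <- simulate_swarm(p, n_steps = 1, n_particles = 5, seed = 96)
  spec1 <- model_spec(alignment = FALSE)
  spec2 <- model_spec(alignment = FALSE, bounds = list(noise_sd = c(0.3, 0.9)))
  g1 <- make_grid(spec1, resolution = 2)
  g2 <- make_grid(spec2, resolution = 2)
  hand_evidence <- function(g, spec) {
    pts <- tidy(g)
    ll <- vapply(seq_len(nrow(pts)), function(i) {
      pars <- model_params(
        attraction_weight = pts$attraction_weight[i],
        interaction_radius = pts$interaction_radius[i],
        blind_angle = pts$blind_angle[i],
        noise_sd = pts$noise_sd[i],
        speed = p$speed, arena_size = p$arena_size
      )
      trajectory_loglik(traj, pars, spec)
    }, numeric(1))
    log(sum(exp(g$log_prior + ll)))
  }
  p1 <- update_posterior(posterior(g1), traj)
  p2 <- update_posterior(posterior(g2), traj)
  expect_equal(
    log_bayes_factor(p1, p2),
    hand_evidence(g1, spec1) - hand_evidence(g2, spec2),
    tolerance = 1e-10
  )
})
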