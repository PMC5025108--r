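test_that("the inertia schedule decays linearly from 0.9 to 0.4", {
  expect_equal(inertia(0, 100), 0.9)
  expect_equal(inertia(100, 100), 0.4)
  expect_equal(inertia(50, 100), 0.65)
  expect_error(inertia(0, 0), "positive")
})

test_that("scaled particles always satisfy the ICM parameter constraints", {
  cfg <- swarm_config()
  set.seed(31)
  for (rep in 1:200) {
    p <- runif(4, -0.2, 1.2)  # deliberately beyond the box; clipping applies
    params <- scale_particle(p, cfg)
    expect_true(0 < params$g && params$g < params$f && params$f < 1)
    expect_lt(params$h, 0)
    expect_gte(params$h, -cfg$h_high)
    expect_lte(params$h, -cfg$h_low)
    expect_true(params$n_iterations %in% 1:5)
  }
})

test_that("scaling endpoints map to the declared parameter extremes", {
  cfg <- swarm_config()
  lo <- scale_particle(c(0, 0, 0, 0), cfg)
  expect_equal(lo$f, 0.05)
  expect_equal(lo$g, 0.0025)
  expect_equal(lo$h, -cfg$h_low)
  expect_equal(lo$n_iterations, 1L)
  hi <- scale_particle(c(1, 1, 1, 1), cfg)
  expect_equal(hi$f, 0.99)
  expect_equal(hi$g, 0.99 * 0.95)
  expect_equal(hi$h, -cfg$h_high)
  expect_equal(hi$n_iterations, 5L)
})

test_that("velocity update algebra and clamping", {
  x <- c(0.5, 0.5, 0.5, 0.5)
  # cognitive and social terms vanish when x = pbest = gbest
  v <- update_velocity(c(0.1, -0.1, 0.2, 0), x, x, x, w = 0.7,
                       c1 = 2, c2 = 2, r1 = runif(4), r2 = runif(4),
                       v_max = 1)
  expect_equal(v, 0.7 * c(0.1, -0.1, 0.2, 0))
  # v = 0, r1 = r2 = 1, pbest = gbest: v' = 4 (gbest - x) before clamping
  g <- c(0.6, 0.4, 0.55, 0.5)
  v2 <- update_velocity(rep(0, 4), x, g, g, w = 0.9, c1 = 2, c2 = 2,
                        r1 = rep(1, 4), r2 = rep(1, 4), v_max = 10)
  expect_equal(v2, 4 * (g - x))
  # clamping bounds every component
  v3 <- update_velocity(rep(0, 4), x, g, g, w = 0.9, c1 = 2, c2 = 2,
                        r1 = rep(1, 4), r2 = rep(1, 4), v_max = 0.1)
  expect_true(all(abs(v3) <= 0.1))
})

test_that("position update adds velocity and clips to the unit box", {
  expect_equal(update_position(c(0.5, 0.2), c(0, 0)), c(0.5, 0.2))
  expect_equal(update_position(0.5, 0.2), 0.7)
  expect_equal(update_position(0.9, 0.5), 1.0)
  expect_equal(update_position(0.1, -0.5), 0.0)
})

test_that("the swarm solves the sphere surrogate", {
  target <- c(0.3, 0.7, 0.2, 0.6)
  sphere <- function(p) sum((p - target)^2)
  res <- pso_minimize(sphere, d = 4,
                      config = swarm_config(population = 50,
                                            max_iterations = 100,
                                            seed = 123, patience = Inf))
  expect_lt(sqrt(sum((res$gbest - target)^2)), 0.05)
  expect_true(all(diff(res$convergence_trace) <= 0))
})

test_that("gbest traces are non-increasing for any seed", {
  rosen <- function(p) {
    sum(100 * (p[-1] - p[-4]^2)^2 + (1 - p[-4])^2)
  }
  for (sd in 1:5) {
    res <- pso_minimize(rosen, d = 4,
                        config = swarm_config(population = 10,
                                              max_iterations = 20, seed = sd))
    expect_true(all(diff(res$convergence_trace) <= 0))
    expect_lte(res$evaluations_used, 10 * 21)
  }
})

test_that("a fixed seed makes the whole run reproducible", {
  noisyf <- function(p) sum(p^2) + runif(1, 0, 1e-6)
  cfg <- swarm_config(population = 8, max_iterations = 15, seed = 77)
  a <- pso_minimize(noisyf, d = 4, config = cfg)
  b <- pso_minimize(noisyf, d = 4, config = cfg)
  expect_identical(a$gbest, b$gbest)
  expect_identical(a$convergence_trace, b$convergence_trace)
})

test_that("zero-iteration budget returns the best initial particle", {
  cfg <- swarm_config(population = 5, max_iterations = 0, seed = 9)
  res <- pso_minimize(function(p) sum(p), d = 4, config = cfg)
  expect_equal(res$evaluations_used, 5L)
  expect_length(res$convergence_trace, 1L)
})

test_that("tuned ICM parameters beat random draws at equal budget", {
  scene <- small_scene(seed = 4)
  s <- apply_log(scene$image)
  fit <- fitness_config()
  opt <- tune_icm(scene$image, s,
                  swarm = swarm_config(population = 20, max_iterations = 10,
                                       seed = 1),
                  fitness = fit)
  expect_true(all(diff(opt$convergence_trace) <= 0))
  set.seed(2)
  rand_best <- min(vapply(1:20, function(i) {
    params <- scale_particle(runif(4), swarm_config())
    mask <- run_icm(s, params)$mask
    fitness_error(mutual_information(scene$image, mask), fit)
  }, numeric(1)))
  expect_lte(opt$best_fitness, rand_best)
})
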