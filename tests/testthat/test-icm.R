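test_that("parameter validation enforces the network's constraints", {
  expect_s3_class(icm_params(0.9, 0.8, -1, 5), "icm_params")
  expect_error(icm_params(0.8, 0.9, -1, 5), "0 < g < f < 1")
  expect_error(icm_params(1.1, 0.5, -1, 5), "0 < g < f < 1")
  expect_error(icm_params(0.9, 0.8, 0.5, 5), "negative")
  expect_error(icm_params(0.9, 0.8, -1, 0), "n_iterations")
  expect_error(icm_params(0.9, 0.8, -1, 5, e_init = 0.5), "e_init")
})

test_that("the default link kernel weights self and 4-neighbours", {
  w <- icm_weights()
  expect_equal(w[2, 2], 1)
  expect_equal(w[1, 2], 0.01)
  expect_equal(w[2, 1], 0.01)
  expect_equal(sum(w), 1.04)
})

test_that("initial state: F and Y zero, E uniformly at e_init", {
  img <- matrix(runif(12), 3, 4)
  st <- icm_init(img, icm_params(0.9, 0.8, -1, 3, e_init = 5))
  expect_equal(st$F, matrix(0, 3, 4))
  expect_equal(st$E, matrix(5, 3, 4))
  expect_equal(st$Y, matrix(0, 3, 4))
  expect_identical(st$iteration, 0L)
})

test_that("isolated-pixel firing dynamics match the scalar recurrence", {
  # S = 0.5, f = 0.9, g = 0.8, h = -1, E0 = 5: fires first at iteration 6;
  # at iteration 5 the comparison is F = 2.04755 against E = 2.048
  ref <- scalar_icm(s = 0.5, f = 0.9, g = 0.8, h = -1, e_init = 5, n = 12)
  expect_false(any(ref$fired[1:5]))
  expect_true(ref$fired[6])
  expect_equal(ref$F[5], 2.04755, tolerance = 1e-12)
  expect_equal(5 * 0.8^4, 2.048)  # threshold it failed to beat
  # after the first firing E = 0.8 * 1.6384 - 1
  expect_equal(ref$E[6], 0.31072, tolerance = 1e-12)
  # re-fires at every subsequent iteration
  expect_true(all(ref$fired[6:12]))

  # the full network reproduces the scalar recurrence on a lone pixel
  s <- matrix(0, 5, 5)
  s[3, 3] <- 0.5
  p <- icm_params(0.9, 0.8, -1, 12, e_init = 5)
  hist <- run_icm(s, p, history = TRUE)$history
  fired <- vapply(hist, function(y) y[3, 3] == 1, logical(1))
  expect_equal(fired, ref$fired)
})

test_that("guaranteed firing and persistent re-firing on scalar recurrences", {
  set.seed(3)
  for (rep in 1:25) {
    f <- runif(1, 0.1, 0.99)
    g <- runif(1, 0.05, 0.95) * f
    h <- -runif(1, 1, 10)
    s <- runif(1, 0.05, 1)
    ref <- scalar_icm(s, f, g, h, e_init = 5, n = 200)
    first <- which(ref$fired)[1]
    expect_false(is.na(first))  # E decays to 0, F climbs to >= S
    expect_true(all(ref$fired[first:200]))  # h <= -1 keeps it firing
  }
})

test_that("a fired pixel feeds 0.01 to 4-neighbours and 1 to itself", {
  s <- matrix(0, 3, 3)
  s[2, 2] <- 1
  p <- icm_params(0.5, 0.4, -1, 2, e_init = 1.2)
  st <- icm_init(s, p)
  st1 <- icm_step(st, s, p)   # centre fires: F = 1 > E = 1.2? no -> F=1
  expect_equal(st1$Y[2, 2], 0)
  st2 <- icm_step(st1, s, p)  # F = 0.5 + 1 = 1.5 > E = 0.48 -> fires
  expect_equal(st2$Y[2, 2], 1)
  st3 <- icm_step(st2, s, p)
  # neighbour feeding: 4-neighbours received 0.01, diagonals nothing,
  # the centre received its own pulse through the unit self-weight
  expect_equal(st3$F[1, 2], 0.01)
  expect_equal(st3$F[2, 1], 0.01)
  expect_equal(st3$F[1, 1], 0)
  expect_equal(st3$F[2, 2], 0.5 * 1.5 + 1 + 1)
})

test_that("run_icm matches the per-pixel loop oracle on random grids", {
  set.seed(99)
  for (rep in 1:50) {
    s <- matrix(runif(64), 8, 8)
    p <- random_icm_params()
    ours <- run_icm(s, p, history = TRUE)
    ref <- icm_reference(s, p)
    expect_identical(ours$mask, ref$mask)
    for (it in seq_along(ref$history)) {
      expect_identical(ours$history[[it]], ref$history[[it]])
    }
  }
})

test_that("run_icm agrees with iterating icm_step", {
  set.seed(5)
  s <- matrix(runif(120), 10, 12)
  p <- icm_params(0.7, 0.3, -2, 4)
  st <- icm_init(s, p)
  for (k in 1:4) st <- icm_step(st, s, p)
  expect_equal(run_icm(s, p)$mask, st$Y)
})

test_that("one iteration with a high threshold yields an all-zero mask", {
  s <- matrix(runif(100), 10, 10)  # S <= 1 < e_init
  p <- icm_params(0.9, 0.5, -1, 1, e_init = 5)
  expect_equal(run_icm(s, p)$mask, matrix(0, 10, 10))
})

test_that("a constant image pulses spatially uniformly at every iteration", {
  s <- matrix(0.6, 9, 9)
  p <- icm_params(0.8, 0.3, -1, 5)
  hist <- run_icm(s, p, history = TRUE)$history
  for (y in hist) expect_true(all(y == y[1, 1]))
})

test_that("identical inputs give identical masks", {
  s <- matrix(runif(200), 10, 20)
  p <- icm_params(0.85, 0.44, -3, 4)
  expect_identical(run_icm(s, p)$mask, run_icm(s, p)$mask)
})

test_that("adding a fired neighbour cannot decrease the next feeding", {
  set.seed(21)
  s <- matrix(runif(49), 7, 7)
  p <- icm_params(0.8, 0.4, -1, 3)
  st <- icm_init(s, p)
  base <- icm_step(st, s, p)
  boosted <- st
  boosted$Y[4, 4] <- 1  # force one extra fired neighbour in the previous pulse
  boosted <- icm_step(boosted, s, p)
  expect_true(all(boosted$F >= base$F))
})

test_that("shape mismatches are rejected", {
  s <- matrix(0.5, 4, 4)
  p <- icm_params(0.9, 0.8, -1, 2)
  st <- icm_init(matrix(0, 5, 5), p)
  expect_error(icm_step(st, s, p), "does not match")
})
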