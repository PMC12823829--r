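test_that("zero noise collapses the simulation to the deterministic curve", {
  p <- decay_params()
  grid <- seq(0, 40, by = 2)
  s <- simulate_curve(p, grid, mc_config(n_iter = 100, noise_sigma = 0, seed = 1))
  det <- survival_at(p, grid)
  expect_identical(s$mean, det)
  expect_identical(s$lower, det)
  expect_identical(s$upper, det)
})

test_that("a fixed seed makes the simulation fully reproducible", {
  p <- decay_params()
  cfg <- mc_config(n_iter = 500, noise_sigma = 0.02, seed = 99)
  s1 <- simulate_curve(p, 0:20, cfg)
  s2 <- simulate_curve(p, 0:20, cfg)
  expect_identical(s1, s2)
  s3 <- simulate_curve(p, 0:20, mc_config(n_iter = 500, noise_sigma = 0.02,
                                          seed = 100))
  expect_false(identical(s1$mean, s3$mean))
})

test_that("simulation matches an independent loop implementation draw for draw", {
  p <- decay_params()
  grid <- c(0, 5, 10.2, 22.6, 40)
  cfg <- mc_config(n_iter = 2000, noise_sigma = 0.02, seed = 7)
  s <- simulate_curve(p, grid, cfg)
  oracle <- mc_summary_by_loop(p, grid, n_iter = 2000, sigma = 0.02, seed = 7)
  expect_equal(s$mean, oracle[, 1], tolerance = 1e-15)
  expect_equal(s$lower, oracle[, 2], tolerance = 1e-15)
  expect_equal(s$upper, oracle[, 3], tolerance = 1e-15)
})

test_that("the Monte Carlo mean converges to the deterministic value (CLT bound)", {
  p <- decay_params()
  sigma <- 0.02
  n <- 10000
  s <- simulate_curve(p, 10.2, mc_config(n_iter = n, noise_sigma = sigma,
                                         seed = 11))
  det <- survival_at(p, 10.2)  # ~0.477, far from the clipping boundaries
  expect_lt(abs(s$mean - det), 4 * sigma / sqrt(n))
})

test_that("reported percentiles equal a sort-based brute-force on the same draws", {
  p <- decay_params()
  cfg <- mc_config(n_iter = 1001, noise_sigma = 0.05, seed = 3,
                   interval = c(10, 90))
  s <- simulate_curve(p, c(8, 16), cfg)
  oracle <- mc_summary_by_loop(p, c(8, 16), 1001, 0.05, seed = 3,
                               interval = c(10, 90))
  expect_equal(s$lower, oracle[, 2], tolerance = 1e-15)
  expect_equal(s$upper, oracle[, 3], tolerance = 1e-15)
})

test_that("draws are clipped so every summary stays within [0, 1]", {
  p <- decay_params()
  s <- simulate_curve(p, 0:40, mc_config(n_iter = 200, noise_sigma = 1,
                                         seed = 5))
  for (col in c("mean", "lower", "upper")) {
    expect_true(all(s[[col]] >= 0 & s[[col]] <= 1))
  }
  expect_true(all(s$lower <= s$mean & s$mean <= s$upper))
})

test_that("interval width grows with sigma and vanishes as sigma -> 0", {
  p <- decay_params()
  widths <- vapply(c(0, 0.005, 0.02, 0.05), function(sg) {
    s <- simulate_curve(p, 15, mc_config(n_iter = 4000, noise_sigma = sg,
                                         seed = 21))
    s$upper - s$lower
  }, numeric(1))
  expect_true(all(diff(widths) > 0 | widths[-1] == 0))
  expect_identical(widths[1], 0)
})

test_that("the 95% simulation interval covers ~95% of fresh noisy draws", {
  p <- decay_params()
  sigma <- 0.02
  band <- simulate_curve(p, 15, mc_config(n_iter = 10000, noise_sigma = sigma,
                                          seed = 31))
  set.seed(32)
  fresh <- survival_at(p, 15) + rnorm(10000, 0, sigma)
  fresh <- pmin(pmax(fresh, 0), 1)
  coverage <- mean(fresh >= band$lower & fresh <= band$upper)
  expect_lt(abs(coverage - 0.95), 0.01)
})

test_that("time-mode noise perturbs the delay instead of the probability", {
  p <- decay_params()
  cfg <- mc_config(n_iter = 5000, noise_sigma = 2, noise_mode = "time",
                   seed = 13)
  s <- simulate_curve(p, 20, cfg)
  # E[(1-r)^(t+eps)] = (1-r)^t * E[(1-r)^eps] = (1-r)^t * exp((log(1-r))^2 sigma^2 / 2)
  lognoise <- exp((log(1 - p$r))^2 * 2^2 / 2)
  expected <- survival_at(p, 20) * lognoise
  expect_lt(abs(s$mean - expected), 0.01)
  expect_true(all(s$lower >= 0 & s$upper <= 1))
})

test_that("scenario simulation agrees with the deterministic scenario value", {
  p <- decay_params()
  luroy <- study_cohort()[3, ]

  noiseless <- simulate_scenario(luroy, p, 5,
                                 mc_config(n_iter = 100, noise_sigma = 0,
                                           seed = 1))
  expect_lt(abs(100 * noiseless$mean - 13.3), 0.1)

  base <- simulate_scenario(luroy, p, 0,
                            mc_config(n_iter = 100, noise_sigma = 0, seed = 1))
  expect_identical(base$mean, survival_at(p, 32.8))

  sigma <- 0.05
  n <- 10000
  noisy <- simulate_scenario(luroy, p, 5,
                             mc_config(n_iter = n, noise_sigma = sigma,
                                       seed = 17))
  det <- scenario_survival(luroy, p, 5)$survival
  expect_lt(abs(noisy$mean - det), 4 * sigma / sqrt(n))
})

test_that("invalid Monte Carlo configurations are rejected", {
  expect_error(mc_config(n_iter = 0), "n_iter")
  expect_error(mc_config(noise_sigma = -0.1), "noise_sigma")
  expect_error(mc_config(interval = c(97.5, 2.5)), "interval")
  expect_error(mc_config(interval = c(-1, 97.5)), "interval")
})

test_that("simulate_curve leaves the caller's RNG stream untouched", {
  set.seed(1234)
  before <- runif(1)
  set.seed(1234)
  invisible(simulate_curve(decay_params(), 0:5,
                           mc_config(n_iter = 50, seed = 8)))
  after <- runif(1)
  expect_identical(before, after)
})
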