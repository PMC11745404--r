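test_that("Euler-Maruyama steps accumulate and respect fixed points", {
  f2 <- as_change_model(function(x) rep(2, length(x)))
  g0 <- noise_model_fn(0)
  x <- 10
  for (i in 1:5) x <- em_step(x, f2, g0, 0.1, 0)
  expect_equal(x, 11)
  flog <- as_change_model(function(x) 0.3 * x * (1 - x / 60))
  expect_equal(em_step(60, flog, g0, 0.1, 0), 60)
  expect_equal(em_step(0, flog, g0, 0.1, 0), 0)
  # clipping at the boundary
  expect_equal(em_step(99.9, f2, g0, 0.5, 0), 100)
})

test_that("OU stationary spread matches the closed form sigma/sqrt(2*theta)", {
  f <- as_change_model(function(x) -0.5 * (x - 50))
  ens <- simulate_ensemble(data.frame(cover = rep(50, 10000), mat = 0), f,
                           noise_model_fn(3),
                           simulation_config(dt = 0.1, steps = 2000, seed = 5))
  s <- stats::sd(ensemble_snapshot(ens, 200))
  expect_lt(abs(s - 3) / 3, 0.05)
})

test_that("ensembles are reproducible and zero-noise runs are dt-stable", {
  f <- as_change_model(function(x) 0.3 * x * (1 - x / 60))
  init <- data.frame(cover = c(5, 30, 80), mat = 0)
  e1 <- simulate_ensemble(init, f, noise_model_fn(0),
                          simulation_config(dt = 0.1, steps = 1000, seed = 1))
  e1b <- simulate_ensemble(init, f, noise_model_fn(0),
                           simulation_config(dt = 0.1, steps = 1000, seed = 1))
  expect_identical(e1$latent, e1b$latent)
  e2 <- simulate_ensemble(init, f, noise_model_fn(0),
                          simulation_config(dt = 0.05, steps = 2000, seed = 1))
  expect_lt(max(abs(ensemble_snapshot(e1, 100) - ensemble_snapshot(e2, 100))), 0.1)
  # noisy runs too are seed-reproducible
  e3 <- simulate_ensemble(init, f, noise_model_fn(2),
                          simulation_config(steps = 100, seed = 9))
  e3b <- simulate_ensemble(init, f, noise_model_fn(2),
                           simulation_config(steps = 100, seed = 9))
  expect_identical(e3$latent, e3b$latent)
})

test_that("observation noise widens snapshots by the prescribed amount", {
  f0 <- as_change_model(function(x) rep(0, length(x)))
  ens <- simulate_ensemble(data.frame(cover = rep(50, 100000), mat = 0), f0,
                           noise_model_fn(0),
                           simulation_config(dt = 1, steps = 1, seed = 2,
                                             record_every = 1))
  # h == 0: observed identical to latent
  e0 <- add_observation_noise(ens, noise_model_fn(0, observation = 0), seed = 3)
  expect_identical(e0$observed, e0$latent)
  # h == 5 about a common latent value: SD within 2% of 5
  e5 <- add_observation_noise(ens, noise_model_fn(0, observation = 5), seed = 3)
  expect_lt(abs(stats::sd(ensemble_snapshot(e5, 1, "observed")) - 5) / 5, 0.02)
  e5b <- add_observation_noise(ens, noise_model_fn(0, observation = 5), seed = 3)
  expect_identical(e5$observed, e5b$observed)
  # bounded output
  expect_true(all(e5$observed >= 0 & e5$observed <= 100))
})

test_that("observed densities are at least as wide as latent ones", {
  f <- as_change_model(function(x) 0.3 * x * (1 - x / 60))
  ens <- simulate_ensemble(data.frame(cover = runif(4000, 20, 90), mat = 0), f,
                           noise_model_fn(2),
                           simulation_config(steps = 300, seed = 7))
  ens <- add_observation_noise(ens, noise_model_fn(0, observation = 3), seed = 8)
  for (tt in c(10, 30)) {
    iqr_lat <- stats::IQR(ensemble_snapshot(ens, tt, "latent"))
    iqr_obs <- stats::IQR(ensemble_snapshot(ens, tt, "observed"))
    expect_gte(iqr_obs, iqr_lat)
  }
})

test_that("warming re-resolves bins at the predicted crossing years", {
  b <- temperature_bins()
  f <- as_change_model(function(x) rep(0, length(x)))
  models <- structure(stats::setNames(list(f, f), c("28", "29")),
                      bins = b, class = "change_model_set")
  # plot at MAT -0.25 (bin 28); +0.04 degC/y crosses 0 at year 6.25
  w <- generate_warming(0, 0.04, 12)
  ens <- simulate_ensemble(data.frame(cover = 50, mat = -0.25), models,
                           noise_model_fn(0),
                           simulation_config(steps = 120, seed = 1),
                           bins = b, warming = w)
  expect_equal(unname(ens$bin_path[1, ]), c(rep(28L, 7), rep(29L, 5)))
})

test_that("plots beyond the warmest fitted bin fall back to the warmest model", {
  b <- temperature_bins()
  up <- as_change_model(function(x) rep(1, length(x)))
  down <- as_change_model(function(x) rep(-1, length(x)))
  models <- structure(stats::setNames(list(up, down), c("10", "20")),
                      bins = b, class = "change_model_set")
  # MAT in bin 40: resolved to fitted bin 20 (drift -1); cold plot to bin 10
  ens <- simulate_ensemble(data.frame(cover = c(50, 50), mat = c(5.9, -14)),
                           models, noise_model_fn(0),
                           simulation_config(steps = 10, seed = 1), bins = b)
  expect_equal(ensemble_snapshot(ens, 1), c(49, 51))
})
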