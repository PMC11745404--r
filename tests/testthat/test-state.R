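test_that("equilibria of known drifts are found and classified", {
  eq <- find_equilibria(function(x) 0.1 * x * (1 - x / 60))
  expect_equal(eq$root, c(0, 60), tolerance = 1e-3)
  expect_equal(eq$stability, c("unstable", "stable"))

  eq2 <- find_equilibria(function(x) 0.1 * x * (1 - x / 60) * (x / 20 - 1))
  expect_equal(eq2$root, c(0, 20, 60), tolerance = 1e-3)
  expect_equal(eq2$stability, c("stable", "unstable", "stable"))

  expect_equal(nrow(find_equilibria(function(x) rep(0.5, length(x)))), 0)

  # drift pushing into the lower boundary: a stable boundary equilibrium,
  # reported only on request
  expect_equal(nrow(find_equilibria(function(x) -0.1 - 0.01 * x)), 0)
  eq3 <- find_equilibria(function(x) -0.1 - 0.01 * x, include_boundaries = TRUE)
  expect_equal(eq3$root, 0)
  expect_equal(eq3$stability, "stable")
  expect_equal(eq3$type, "boundary")

  # crossing stabilities alternate
  eq4 <- find_equilibria(function(x) sin(x / 8))
  cr <- eq4[eq4$type == "crossing", ]
  expect_true(all(cr$stability[-1] != cr$stability[-nrow(cr)]))
})

test_that("density landscapes are normalized, reflected and flat where they should be", {
  set.seed(51)
  for (vals in list(runif(500, 0, 100), rnorm(500, 3, 4), rnorm(300, 98, 5))) {
    dl <- density_landscape(pmin(100, pmax(0, vals)))
    expect_lt(abs(trapz_(dl$cover, dl$density) - 1), 1e-6)
    expect_true(all(dl$density >= 0))
  }
  # uniform cover: density close to 1/100 away from the edges
  u <- runif(100000, 0, 100)
  du <- density_landscape(u)
  mid <- du$density[du$cover >= 10 & du$cover <= 90]
  expect_lt(max(abs(mid - 0.01) / 0.01), 0.10)
  # mass far from boundaries: reflection is a no-op vs a plain Gaussian KDE
  v <- rnorm(500, 50, 5)
  dl <- density_landscape(v, bw = 2)
  plain <- sapply(dl$cover, function(g) mean(stats::dnorm(g, v, 2)))
  plain <- plain / trapz_(dl$cover, plain)
  expect_lt(max(abs(dl$density - plain)), 1e-9)
  expect_error(density_landscape(50), "at least 2")
})

test_that("modes of a mixture are detected and ripples suppressed", {
  set.seed(53)
  v <- c(rnorm(25000, 10, 3), rnorm(25000, 60, 5))
  m <- find_modes(density_landscape(pmin(100, pmax(0, v))))
  expect_equal(nrow(m), 2)
  expect_lt(abs(sort(m$cover)[1] - 10), 2)
  expect_lt(abs(sort(m$cover)[2] - 60), 2)
  # a bump below the prominence floor is not a mode
  g <- seq(0, 100, by = 0.1)
  d <- stats::dnorm(g, 50, 8) + 0.004 * stats::dnorm(g, 90, 1)
  fake <- structure(data.frame(cover = g, density = d / trapz_(g, d)),
                    class = c("density_landscape", "data.frame"))
  expect_equal(nrow(find_modes(fake)), 1)
})

test_that("windowed densities pool correctly and track drift direction", {
  p <- make_logistic_panel(800, seed = 57, init = 60)
  # a single window spanning everything equals the plain pooled density
  wd <- windowed_densities(p, windows = list(c(2000, 2020)))
  pooled <- density_landscape(as.vector(panel_cover(p)), window = "2000-2020")
  expect_equal(wd[["2000-2020"]]$density, pooled$density)

  # stationarity after burn-in: early and late windows agree in
  # distribution (KS)
  ps <- make_logistic_panel(800, seed = 58, init = 60, years = 41)
  V <- panel_cover(ps)
  yrs <- panel_years(ps)
  early <- as.vector(V[, yrs >= 2020 & yrs <= 2024])
  late <- as.vector(V[, yrs >= 2036 & yrs <= 2040])
  ks <- suppressWarnings(stats::ks.test(early, late))
  expect_lt(unname(ks$statistic), 0.05)

  # drifting panel: window modes move monotonically toward the attractor
  pd <- make_logistic_panel(2000, seed = 59, K = 45, g = 1, init = 10)
  wdd <- windowed_densities(pd)
  modes <- sapply(wdd, function(d) find_modes(d)$cover[1])
  expect_true(all(diff(modes) > 0))
  expect_true(all(modes <= 46))

  expect_error(windowed_densities(p, windows = list(c(1990, 1995))), "no observed years")
})

test_that("zero-noise projections land on reported stable equilibria", {
  f <- function(x) 0.1 * x * (1 - x / 60) * (x / 20 - 1)
  eq <- find_equilibria(f)
  stable <- eq$root[eq$stability == "stable"]
  ens <- simulate_ensemble(data.frame(cover = c(5, 15, 25, 90), mat = 0),
                           as_change_model(f), noise_model_fn(0),
                           simulation_config(steps = 3000, seed = 1))
  final <- ensemble_snapshot(ens, 300)
  for (x in final)
    expect_lt(min(abs(x - stable)), 0.5)
})
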