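test_that("lagged SD table matches a brute-force oracle and basic cases", {
  # constant series: every (group, lag) SD is exactly 0
  V <- matrix(50, 40, 21)
  p <- cover_panel(sprintf("p%d", 1:40), runif(40, -1, 1), V, 2000:2020)
  tab <- build_lag_sd(p, min_n = 10)
  expect_true(all(tab$sd == 0))

  # random panel: agrees exactly with naive loops
  set.seed(31)
  V2 <- matrix(runif(30 * 12, 0, 100), 30, 12)
  p2 <- cover_panel(sprintf("p%d", 1:30), runif(30, -1, 1), V2, 2000:2011)
  tab2 <- build_lag_sd(p2, max_lag = 3, min_n = 2)
  orc <- oracle_lag_sd(V2, max_lag = 3, min_n = 2)
  expect_equal(as.data.frame(tab2), orc, tolerance = 1e-12)

  # relabeling invariance
  perm <- sample(30)
  p3 <- cover_panel(sprintf("q%d", 1:30), p2$mat[perm], V2[perm, ], 2000:2011)
  expect_equal(as.data.frame(build_lag_sd(p3, max_lag = 3, min_n = 2)), orc,
               tolerance = 1e-12)

  expect_error(build_lag_sd(p2, max_lag = 20), "max_lag")
  expect_error(build_lag_sd(p, min_n = 1e6), "min_n")
})

test_that("sqrt-lag regression solves exact configurations", {
  tab <- structure(data.frame(cover_group = 50, lag = c(1, 4, 9),
                              sd = c(3, 4, 5), n = 100),
                   class = c("lag_sd_table", "data.frame"))
  co <- fit_sqrt_lag(tab)
  expect_equal(co$a, 2, tolerance = 1e-10)
  expect_equal(co$b, 1, tolerance = 1e-10)
  expect_false(co$clipped)

  # lag-independent SD: all observation noise
  tab2 <- structure(data.frame(cover_group = 40, lag = 1:10, sd = 2.5, n = 50),
                    class = c("lag_sd_table", "data.frame"))
  co2 <- fit_sqrt_lag(tab2)
  expect_equal(co2$a, 2.5, tolerance = 1e-10)
  expect_equal(co2$b, 0, tolerance = 1e-10)

  # decreasing SD: negative slope clipped to zero and flagged
  tab3 <- structure(data.frame(cover_group = 30, lag = c(1, 4, 9),
                               sd = c(5, 3, 1), n = 50),
                    class = c("lag_sd_table", "data.frame"))
  co3 <- fit_sqrt_lag(tab3)
  expect_equal(co3$b, 0)
  expect_true(co3$clipped)

  # variance-scale method on exactly linear variance: recovers (a, b)
  tab4 <- structure(data.frame(cover_group = 50, lag = 1:10,
                               sd = sqrt(2 * 2^2 + 1 * (1:10)), n = 100),
                    class = c("lag_sd_table", "data.frame"))
  co4 <- fit_sqrt_lag(tab4, method = "variance")
  expect_equal(co4$a, 2, tolerance = 1e-10)
  expect_equal(co4$b, 1, tolerance = 1e-10)

  # a group with too few lags is skipped with a warning, the rest survive
  mixed <- structure(data.frame(cover_group = c(10, 10, 20, 20, 20),
                                lag = c(1, 2, 1, 4, 9),
                                sd = c(1, 1, 3, 4, 5), n = 5),
                     class = c("lag_sd_table", "data.frame"))
  expect_warning(co5 <- fit_sqrt_lag(mixed), "skipped")
  expect_equal(co5$cover_group, 20)
  expect_equal(co5$a, 2, tolerance = 1e-10)
})

test_that("noise smooths recover constant and linear coefficient fields", {
  co <- structure(data.frame(cover_group = seq(5, 95, by = 5), a = 2, b = 1,
                             a_raw = 2, b_raw = 1, r2 = 1, clipped = FALSE),
                  class = c("noise_coefficients", "data.frame"))
  nm <- fit_noise_models(co)
  xs <- seq(5, 95, by = 1)
  expect_lt(max(abs(nm$observation(xs) - 2)), 1e-6)
  expect_lt(max(abs(nm$process(xs) - 1)), 1e-6)

  co2 <- co
  co2$b <- 0.5 + 0.02 * co2$cover_group
  nm2 <- fit_noise_models(co2)
  expect_lt(max(abs(nm2$process(xs) - (0.5 + 0.02 * xs))), 1e-3)

  # clipped-at-zero contract
  co3 <- co
  co3$a <- pmax(0, -5 + 0.02 * co3$cover_group)
  nm3 <- fit_noise_models(co3)
  expect_true(all(nm3$observation(seq(0, 100)) >= 0))
  expect_error(fit_noise_models(co[1:5, ]), "min_groups")
})

test_that("with no observation noise the intercepts center at zero", {
  gt <- ground_truth("custom", drift_fn = function(x) rep(0, length(x)),
                     process_noise = 1, obs_noise = 0)
  p <- generate_panel(gt, synthetic_config(2000, seed = 37, mat_range = c(-1, 1),
                                           init_range = c(20, 80)))
  co <- suppressWarnings(fit_sqrt_lag(build_lag_sd(p)))
  sel <- co$cover_group >= 20 & co$cover_group <= 80
  expect_lt(abs(stats::median(co$a_raw[sel])), 0.2)
})

test_that("process and observation amplitudes separate independently", {
  recover <- function(g, h, seed) {
    gt <- ground_truth("custom", drift_fn = function(x) rep(0, length(x)),
                       process_noise = g, obs_noise = h)
    p <- generate_panel(gt, synthetic_config(2500, seed = seed,
                                             mat_range = c(-1, 1),
                                             init_range = c(20, 80)))
    co <- suppressWarnings(fit_sqrt_lag(build_lag_sd(p), method = "variance"))
    sel <- co$cover_group >= 20 & co$cover_group <= 80
    c(a = stats::median(co$a[sel]), b = stats::median(co$b[sel]))
  }
  base <- recover(1, 1, 41)
  more_obs <- recover(1, 3, 41)
  more_proc <- recover(2, 1, 41)
  # raising h moves a, leaves b; raising g moves b, leaves a
  expect_gt(more_obs["a"], base["a"] + 1)
  expect_lt(abs(more_obs["b"] - base["b"]), 0.2)
  expect_gt(more_proc["b"], base["b"] + 0.5)
  expect_lt(abs(more_proc["a"] - base["a"]), 0.4)
})
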