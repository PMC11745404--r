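test_that("theil_sen matches hand-computed cases", {
  expect_equal(theil_sen(rep(7, 10)), 0)
  # six pairwise slopes {2, 0.5, 1.667, -1, 1.5, 4}; median = (1.5 + 1.667)/2
  expect_equal(theil_sen(c(10, 12, 11, 15)), mean(c(1.5, 5 / 3)))
  expect_equal(theil_sen(5 + 0.7 * (0:12)), 0.7)
  expect_error(theil_sen(c(3)), "at least 2")
  expect_error(theil_sen(c(3, NA, NA)), "at least 2")
  # missing years skipped, remaining pairs used
  expect_equal(theil_sen(c(10, NA, 14), years = c(0, 1, 2)), 2)
  # zero year differences excluded
  expect_equal(theil_sen(c(1, 9, 2), years = c(0, 0, 1)), stats::median(c(1, -7)))
})

test_that("theil_sen equals the brute-force all-pairs-median oracle", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(2:12, 1)
    v <- round(runif(n, 0, 100), 2)
    yrs <- sort(sample(0:20, n))
    expect_identical(theil_sen(v, yrs), oracle_theil_sen(v, yrs))
  }
})

test_that("bin assignment is total with boundary fallbacks", {
  b <- temperature_bins()
  expect_equal(b$n, 40)
  expect_equal(assign_bin(-13.8, b), 1L)
  expect_equal(assign_bin(5.9, b), 40L)
  expect_equal(assign_bin(6.2, b), 40L)   # beyond warmest: warmest bin
  expect_equal(assign_bin(-20, b), 1L)    # below coldest: coldest bin
  expect_equal(assign_bin(-14, b), 1L)
  expect_equal(assign_bin(-13.5, b), 2L)  # half-open intervals
  expect_error(temperature_bins(-14, 6, 0.3), "not an integer")
})

test_that("the spline reproduces exact structure in the change data", {
  set.seed(2)
  x0 <- runif(400, 10, 70)
  yrs <- 2000:2020
  # linear change field: slope s(x0) = 2 - 0.05 x0, series exactly linear
  V <- sapply(0:20, function(t) x0 + (2 - 0.05 * x0) * t)
  keep <- apply(V >= 0 & V <= 100, 1, all)
  p <- cover_panel(sprintf("p%d", seq_len(sum(keep))),
                   mat = runif(sum(keep), -1, 1), V[keep, ], yrs)
  cm <- fit_change_model(p, one_bin, min_n = 10)
  xs <- seq(ceiling(min(x0[keep])), floor(max(x0[keep])))
  expect_lt(max(abs(predict(cm[[1]], xs) - (2 - 0.05 * xs))), 1e-6)

  # all-zero change: smooth is identically zero
  Vz <- matrix(rep(x0, 21), ncol = 21)
  pz <- cover_panel(sprintf("p%d", seq_along(x0)), runif(length(x0), -1, 1),
                    Vz, yrs)
  cz <- fit_change_model(pz, one_bin, min_n = 10)
  expect_lt(max(abs(predict(cz[[1]], seq(10, 70)))), 1e-8)
})

test_that("fitted smooths are invariant to plot order and panel duplication", {
  set.seed(3)
  p <- make_logistic_panel(400, seed = 13)
  cm <- fit_change_model(p, one_bin, min_n = 10)
  xs <- seq(5, 95, by = 5)
  perm <- sample(nrow(p))
  pp <- cover_panel(p$plot_id[perm], p$mat[perm], panel_cover(p)[perm, ],
                    panel_years(p))
  cmp_ <- fit_change_model(pp, one_bin, min_n = 10)
  expect_equal(predict(cm[[1]], xs), predict(cmp_[[1]], xs), tolerance = 1e-10)
  # duplication invariance, checked where the fit is exact (noise-free
  # linear change field; with noisy data the GCV smoothness re-optimizes)
  x0 <- runif(300, 10, 70)
  V <- sapply(0:20, function(t) x0 + (2 - 0.05 * x0) * t)
  pl <- cover_panel(sprintf("p%d", seq_along(x0)), runif(300, -1, 1), V,
                    2000:2020)
  cml <- fit_change_model(pl, one_bin, min_n = 10)
  pd <- cover_panel(c(paste0(pl$plot_id, "a"), paste0(pl$plot_id, "b")),
                    rep(pl$mat, 2), rbind(V, V), 2000:2020)
  cmd <- fit_change_model(pd, one_bin, min_n = 10)
  xin <- seq(ceiling(min(x0)), floor(max(x0)))
  expect_equal(predict(cml[[1]], xin), predict(cmd[[1]], xin), tolerance = 1e-6)
})

test_that("extrapolation beyond the fitted support is linear", {
  p <- make_logistic_panel(500, seed = 17, init_range = c(30, 70))
  cm <- fit_change_model(p, one_bin, min_n = 10)[[1]]
  lo <- cm$support[1]
  xs <- seq(0, lo - 1, by = 0.5)
  if (length(xs) > 3) {
    y <- predict(cm, xs)
    expect_lt(max(abs(diff(diff(y)))), 1e-8)  # second differences vanish
  }
  hi <- cm$support[2]
  xs2 <- seq(hi + 1, 100, by = 0.5)
  y2 <- predict(cm, xs2)
  expect_lt(max(abs(diff(diff(y2)))), 1e-8)
})

test_that("small groups are skipped and empty panels refused", {
  p <- make_logistic_panel(60, seed = 19)
  expect_error(fit_change_model(p, one_bin, min_n = 1000), "below min_n")
  p2 <- make_logistic_panel(400, seed = 23)
  p2$mat <- c(rep(-1.75, 370), rep(1.75, 30))  # one big and one small bin
  cm <- fit_change_model(p2, temperature_bins(), min_n = 50)
  expect_true(length(attr(cm, "skipped")) >= 1)
  expect_true(length(cm) >= 1)
})

test_that("drift recovery: logistic carrying cover found within 3 cover-%", {
  p <- make_logistic_panel(4000, seed = 29)
  cm <- fit_change_model(p, one_bin, min_n = 100)
  eq <- find_equilibria(cm[[1]])
  stable <- eq$root[eq$stability == "stable"]
  expect_true(any(abs(stable - 60) <= 3))
})
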