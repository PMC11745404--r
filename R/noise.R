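#' Lagged standard deviations by initial-cover group
#'
#' Pools every plot-year occurrence across the panel, groups occurrences by
#' rounded cover (1% groups by default), and for each lag `dt = 1..max_lag`
#' computes the SD of cover `dt` years later across the group. The growth of
#' this SD with lag is what separates process noise (grows like `sqrt(dt)`)
#' from observation noise (lag-independent).
#'
#' @param panel A `cover_panel` whose series span at least `max_lag + 1`
#'   years.
#' @param max_lag Maximum lag in years (default 10).
#' @param group_width Cover group width in % (default 1).
#' @param min_n Minimum occurrences per (group, lag); smaller cells are
#'   omitted (default 30).
#' @return A data frame of class `lag_sd_table` with columns `cover_group`,
#'   `lag`, `sd`, `n`.
#' @export
build_lag_sd <- function(panel, max_lag = 10, group_width = 1, min_n = 30) {
  V <- panel_cover(panel)
  Y <- ncol(V)
  if (Y < max_lag + 1)
    stop_borealstate("build_lag_sd: series span %d years, need >= max_lag + 1 = %d",
                     Y, max_lag + 1)
  grp_all <- integer(0); lag_all <- integer(0); val_all <- numeric(0)
  for (lag in seq_len(max_lag)) {
    t0 <- seq_len(Y - lag)
    x0 <- as.vector(V[, t0, drop = FALSE])
    x1 <- as.vector(V[, t0 + lag, drop = FALSE])
    ok <- !is.na(x0) & !is.na(x1)
    grp_all <- c(grp_all, as.integer(round(x0[ok] / group_width)))
    lag_all <- c(lag_all, rep.int(lag, sum(ok)))
    val_all <- c(val_all, x1[ok])
  }
  key <- grp_all * (max_lag + 1L) + lag_all
  n  <- rowsum(rep(1, length(key)), key)
  s1 <- rowsum(val_all, key)
  s2 <- rowsum(val_all^2, key)
  kv <- as.integer(rownames(n))
  keep <- n[, 1] >= min_n
  if (!any(keep))
    stop_borealstate("build_lag_sd: no (cover group, lag) cell reaches min_n = %d", min_n)
  nn <- n[keep, 1]
  sd <- sqrt(pmax(0, (s2[keep, 1] - s1[keep, 1]^2 / nn) / (nn - 1)))
  out <- data.frame(cover_group = (kv[keep] %/% (max_lag + 1L)) * group_width,
                    lag = kv[keep] %% (max_lag + 1L),
                    sd = sd, n = as.integer(nn))
  out <- out[order(out$cover_group, out$lag), ]
  rownames(out) <- NULL
  structure(out, class = c("lag_sd_table", "data.frame"))
}

#' Separate process and observation noise per cover group
#'
#' For each cover group with at least `min_lags` lags, regresses the lagged
#' SD on the lag. Two regressions are offered:
#' \describe{
#'   \item{`"sqrt-sd"`}{OLS of `sd` on `sqrt(lag)` with intercept: the
#'     intercept is the observation noise `a` and the slope the process
#'     noise `b`, following `sigma(dt) = a + b*sqrt(dt)`.}
#'   \item{`"variance"`}{OLS of `sd^2` on `lag`: under independent Gaussian
#'     noises the group variance is exactly `2a^2 + b^2*dt` (the observation
#'     error of the grouping year enters the spread once more via the
#'     conditioning on observed cover), so `a = sqrt(intercept/2)` and
#'     `b = sqrt(slope)`. This form is exactly linear and recovers the true
#'     amplitudes; see the methods vignette.}
#' }
#' Negative coefficients are clipped to zero and flagged.
#'
#' @param table A [build_lag_sd()] result.
#' @param method `"sqrt-sd"` (default) or `"variance"`.
#' @param min_lags Minimum number of lags per group (default 3); groups with
#'   fewer are skipped with a warning.
#' @param weighted Weight the regression by occurrence counts `n` (default
#'   `FALSE`, plain OLS).
#' @return Data frame of class `noise_coefficients`: `cover_group`, `a`
#'   (observation noise, %), `b` (process noise, % per sqrt-year), `r2`,
#'   `clipped`.
#' @examples
#' tab <- structure(data.frame(cover_group = 50, lag = c(1, 4, 9),
#'                             sd = c(3, 4, 5), n = 100),
#'                  class = c("lag_sd_table", "data.frame"))
#' fit_sqrt_lag(tab)   # a = 2, b = 1
#' @export
fit_sqrt_lag <- function(table, method = c("sqrt-sd", "variance"),
                         min_lags = 3, weighted = FALSE) {
  method <- match.arg(method)
  groups <- split(seq_len(nrow(table)), table$cover_group)
  rows <- lapply(names(groups), function(gname) {
    d <- table[groups[[gname]], , drop = FALSE]
    if (nrow(d) < min_lags) {
      warning(sprintf("cover group %s has %d lags (< %d); skipped",
                      gname, nrow(d), min_lags), call. = FALSE)
      return(NULL)
    }
    w <- if (weighted) d$n else NULL
    if (method == "sqrt-sd") {
      fit <- stats::lm(sd ~ I(sqrt(lag)), data = d, weights = w)
      a_raw <- unname(stats::coef(fit)[1]); b_raw <- unname(stats::coef(fit)[2])
      r2 <- suppressWarnings(summary(fit)$r.squared)
    } else {
      fit <- stats::lm(I(sd^2) ~ lag, data = d, weights = w)
      ic <- unname(stats::coef(fit)[1]); sl <- unname(stats::coef(fit)[2])
      a_raw <- sign(ic) * sqrt(abs(ic) / 2)
      b_raw <- sign(sl) * sqrt(abs(sl))
      r2 <- suppressWarnings(summary(fit)$r.squared)
    }
    data.frame(cover_group = as.numeric(gname),
               a = max(0, a_raw), b = max(0, b_raw),
               a_raw = a_raw, b_raw = b_raw, r2 = r2,
               clipped = (a_raw < 0) | (b_raw < 0))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    stop_borealstate("fit_sqrt_lag: no cover group has >= %d lags", min_lags)
  out <- do.call(rbind, rows)
  out <- out[order(out$cover_group), ]
  rownames(out) <- NULL
  structure(out, method = method, class = c("noise_coefficients", "data.frame"))
}

#' Smooth per-cover noise coefficients into noise functions
#'
#' Fits penalized cubic regression splines of the observation-noise
#' intercepts `a` and process-noise slopes `b` over cover, yielding the
#' temperature-independent noise functions `h(X)` and `g(X)` of the cover
#' model. Outputs are clipped at zero (noise amplitudes are nonnegative).
#'
#' @param coeffs A [fit_sqrt_lag()] result with at least `min_groups` cover
#'   groups.
#' @param k Spline basis dimension (default 10).
#' @param min_groups Minimum cover groups required (default 10).
#' @return An object of class `noise_model` with evaluable elements
#'   `process(x)` and `observation(x)` and the coefficient table.
#' @export
fit_noise_models <- function(coeffs, k = 10, min_groups = 10) {
  if (nrow(coeffs) < min_groups)
    stop_borealstate("fit_noise_models: %d cover groups < min_groups = %d",
                     nrow(coeffs), min_groups)
  kk <- min(k, max(3L, nrow(coeffs) - 1L))
  fit_a <- mgcv::gam(a ~ s(cover_group, bs = "cr", k = kk), data = coeffs,
                     method = "GCV.Cp")
  fit_b <- mgcv::gam(b ~ s(cover_group, bs = "cr", k = kk), data = coeffs,
                     method = "GCV.Cp")
  sup <- range(coeffs$cover_group)
  eval_smooth <- function(fit) {
    force(fit)
    function(x) {
      xc <- pmin(pmax(as.numeric(x), sup[1]), sup[2])  # constant beyond support
      pmax(0, as.numeric(mgcv::predict.gam(fit, newdata = data.frame(cover_group = xc))))
    }
  }
  structure(list(process = eval_smooth(fit_b), observation = eval_smooth(fit_a),
                 coefficients = as.data.frame(coeffs), support = sup,
                 fit_process = fit_b, fit_observation = fit_a),
            class = "noise_model")
}

#' Build a noise model from plain functions or constants
#'
#' @param process Constant or function of cover: diffusion amplitude
#'   (% per sqrt-year).
#' @param observation Constant or function of cover: observation SD (%).
#' @return A `noise_model`.
#' @export
noise_model_fn <- function(process, observation = 0) {
  as_fn <- function(v) {
    if (is.function(v)) function(x) pmax(0, v(x))
    else { force(v); function(x) rep_len(max(0, v), length(x)) }
  }
  structure(list(process = as_fn(process), observation = as_fn(observation),
                 coefficients = NULL, support = c(0, 100)),
            class = "noise_model")
}

#' @export
print.noise_model <- function(x, ...) {
  mid <- c(10, 30, 50, 70, 90)
  cat("Noise model (temperature-independent)\n")
  cat("  process  g(x) at 10/30/50/70/90%: ",
      paste(sprintf("%.2f", x$process(mid)), collapse = " "), "\n")
  cat("  observation h(x) at 10/30/50/70/90%: ",
      paste(sprintf("%.2f", x$observation(mid)), collapse = " "), "\n")
  invisible(x)
}

#' Fit a noise model from a panel in one call
#'
#' Convenience wrapper: [build_lag_sd()] then [fit_sqrt_lag()] then
#' [fit_noise_models()].
#'
#' @inheritParams build_lag_sd
#' @inheritParams fit_sqrt_lag
#' @param k,min_groups Passed to [fit_noise_models()].
#' @return A `noise_model`.
#' @export
fit_noise_from_panel <- function(panel, max_lag = 10, group_width = 1,
                                 min_n = 30, method = "sqrt-sd", k = 10,
                                 min_groups = 10) {
  tab <- build_lag_sd(panel, max_lag = max_lag, group_width = group_width,
                      min_n = min_n)
  co <- fit_sqrt_lag(tab, method = method)
  fit_noise_models(co, k = k, min_groups = min_groups)
}
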