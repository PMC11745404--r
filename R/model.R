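#' Fit a stochastic tree-cover model to a panel
#'
#' The central fitting function: reconstructs the Langevin model
#' `dX = f(X) dt + g(X) dW` (with observation noise `h(X)` superimposed on
#' measurements) from a panel of short annual cover series.
#'
#' Three estimation stages:
#' 1. **Drift** `f(X)`: per-plot Theil-Sen annual change, related to initial
#'    cover by a penalized cubic regression spline, independently per 0.5
#'    degree-Celsius temperature bin (and optional strata).
#' 2. **Noise separation**: the SD of cover `dt` years ahead, pooled over
#'    all plot-year occurrences in 1% cover groups, is regressed on the lag
#'    (`sigma(dt) = a + b*sqrt(dt)`); the lag-independent intercept is the
#'    observation noise, the sqrt-lag slope the process noise.
#' 3. **Noise smooths** `g(X)`, `h(X)`: the per-cover-group coefficients are
#'    smoothed over cover with the same spline contract. A single
#'    temperature-independent noise pair is used.
#'
#' @param panel A `cover_panel` (see [generate_panel()], [read_panel()]).
#' @param bins [temperature_bins()] (default 40 bins of 0.5 degC on
#'   \[-14, 6)).
#' @param strata Optional character vector of panel strata columns to
#'   stratify the drift fits by.
#' @param k Spline basis dimension for all smooths (default 10).
#' @param min_n Minimum plots per (bin, stratum) drift group (default 50).
#' @param max_lag Maximum lag (years) for noise separation (default 10).
#' @param min_n_lag Minimum occurrences per (cover group, lag) cell
#'   (default 30).
#' @param noise_method `"sqrt-sd"` (the SD-on-sqrt-lag regression; default)
#'   or `"variance"` (the exactly linear variance-scale form; see
#'   [fit_sqrt_lag()]).
#' @return An object of class `treecover_model` with elements `change`
#'   (a `change_model_set`), `noise` (a `noise_model`), `changes` (per-plot
#'   trend table), `bins`, `panel_years`.
#' @seealso [simulate.treecover_model()], [find_equilibria()],
#'   [biomass_change()]
#' @examples
#' gt <- ground_truth("logistic", r = 0.3, K = 60, process_noise = 2)
#' p <- generate_panel(gt, synthetic_config(2000, seed = 1, mat_range = c(-1, 1)))
#' m <- fit_treecover_model(p, temperature_bins(-1, 1, 2), min_n = 100)
#' summary(m)
#' @export
fit_treecover_model <- function(panel, bins = temperature_bins(), strata = NULL,
                                k = 10, min_n = 50, max_lag = 10, min_n_lag = 30,
                                noise_method = "sqrt-sd") {
  changes <- panel_changes(panel)
  change <- fit_change_model(panel, bins = bins, strata = strata, k = k,
                             min_n = min_n, changes = changes)
  noise <- fit_noise_from_panel(panel, max_lag = max_lag, min_n = min_n_lag,
                                method = noise_method, k = k)
  structure(list(change = change, noise = noise, changes = changes,
                 bins = bins, strata = strata,
                 panel_years = panel_years(panel), call = match.call()),
            class = "treecover_model")
}

#' @export
print.treecover_model <- function(x, ...) {
  cat("Stochastic tree-cover model (drift-diffusion with observation noise)\n")
  cat(sprintf("  %d plots, years %d-%d\n", nrow(x$changes),
              min(x$panel_years), max(x$panel_years)))
  cat(sprintf("  drift: %d fitted bin group(s) (%d skipped), cubic regression splines\n",
              length(x$change), length(attr(x$change, "skipped"))))
  cat("  noise: one temperature-independent process/observation pair\n")
  invisible(x)
}

#' @export
summary.treecover_model <- function(object, ...) {
  eq <- coef(object)
  out <- list(n_plots = nrow(object$changes),
              n_groups = length(object$change),
              skipped = attr(object$change, "skipped"),
              equilibria = eq,
              noise = object$noise)
  class(out) <- "summary.treecover_model"
  out
}

#' @export
print.summary.treecover_model <- function(x, ...) {
  cat(sprintf("Tree-cover model: %d plots, %d fitted group(s)\n",
              x$n_plots, x$n_groups))
  if (length(x$skipped))
    cat("  skipped groups:", paste(x$skipped, collapse = ", "), "\n")
  cat("Equilibria of fitted drifts:\n")
  print(x$equilibria, row.names = FALSE)
  print(x$noise)
  invisible(x)
}

#' Equilibria of every fitted drift
#'
#' @param object A `treecover_model`.
#' @param ... Passed to [find_equilibria()].
#' @return Data frame: `group`, `bin`, `root`, `stability`, `type`.
#' @export
coef.treecover_model <- function(object, ...) {
  rows <- lapply(names(object$change), function(key) {
    eq <- find_equilibria(object$change[[key]], ...)
    if (!nrow(eq)) return(NULL)
    data.frame(group = key, bin = object$change[[key]]$bin,
               root = eq$root, stability = eq$stability, type = eq$type,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(data.frame(group = character(0), bin = integer(0),
                                       root = numeric(0), stability = character(0),
                                       type = character(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Model predictions over cover
#'
#' @param object A `treecover_model`.
#' @param cover Cover values (%).
#' @param mat MAT used to pick the bin drift (ignored for
#'   `what != "drift"`); alternatively give `bin`.
#' @param bin Bin index (overrides `mat`).
#' @param what `"drift"` (% per year), `"process"` (% per sqrt-year) or
#'   `"observation"` (%).
#' @param stratum Optional stratum key.
#' @param ... Unused.
#' @export
predict.treecover_model <- function(object, cover, mat = NULL, bin = NULL,
                                    what = c("drift", "process", "observation"),
                                    stratum = NULL, ...) {
  what <- match.arg(what)
  if (what == "process") return(object$noise$process(cover))
  if (what == "observation") return(object$noise$observation(cover))
  if (is.null(bin)) {
    if (is.null(mat))
      stop_borealstate("predict: drift prediction needs mat or bin")
    bin <- assign_bin(mat, object$bins)
  }
  key <- resolve_bin_model(object$change, bin, stratum)
  if (length(unique(key)) == 1L)
    return(predict(object$change[[key[1]]], cover))
  vapply(seq_along(cover), function(i)
    predict(object$change[[key[i]]], cover[i]), 0)
}

#' Per-plot residual change
#'
#' Observed Theil-Sen annual change minus the fitted drift at each plot's
#' initial cover.
#'
#' @param object A `treecover_model`.
#' @param ... Unused.
#' @export
residuals.treecover_model <- function(object, ...) {
  ch <- object$changes
  bin <- assign_bin(ch$mat, object$bins)
  stratum <- NULL
  if (!is.null(object$strata))
    stratum <- do.call(paste, c(ch[object$strata], sep = "/"))
  fitted <- numeric(nrow(ch))
  key <- if (is.null(stratum)) resolve_bin_model(object$change, bin)
         else vapply(seq_along(bin), function(i)
           resolve_bin_model(object$change, bin[i], stratum[i]), "")
  for (kk in unique(key)) {
    sel <- key == kk
    fitted[sel] <- predict(object$change[[kk]], ch$x0[sel])
  }
  stats::setNames(ch$change - fitted, ch$plot_id)
}

#' Simulate forward from a fitted tree-cover model
#'
#' Projects an ensemble with [simulate_ensemble()] using the fitted per-bin
#' drifts and the fitted process noise, then (optionally) superimposes the
#' fitted observation noise on the stored snapshots.
#'
#' @param object A `treecover_model`.
#' @param nsim Unused (one ensemble per call); present for the generic.
#' @param seed Integer seed (required).
#' @param init Data frame with `cover` and `mat` (default: the model's own
#'   plots at their initial cover).
#' @param steps,dt,record_every Passed to [simulation_config()].
#' @param warming Optional warming table (see [simulate_ensemble()]).
#' @param observation Add observation noise to snapshots (default `TRUE`).
#' @param stratum Optional stratum key.
#' @param ... Unused.
#' @return A `trajectory_ensemble`.
#' @export
simulate.treecover_model <- function(object, nsim = 1, seed = NULL, init = NULL,
                                     steps = 990, dt = 0.1, record_every = NULL,
                                     warming = NULL, observation = TRUE,
                                     stratum = NULL, ...) {
  if (is.null(seed)) stop_borealstate("simulate: an explicit seed is required")
  init <- init %||% data.frame(cover = object$changes$x0, mat = object$changes$mat)
  cfg <- simulation_config(dt = dt, steps = steps, seed = seed,
                           record_every = record_every)
  ens <- simulate_ensemble(init, object$change, object$noise, cfg,
                           bins = object$bins, warming = warming,
                           stratum = stratum)
  if (observation)
    ens <- add_observation_noise(ens, object$noise, seed = seed + 1L)
  ens
}

#' Plot a fitted tree-cover model
#'
#' Drift curves (change vs cover) for a selection of bins with the zero
#' line and stable/unstable equilibria marked, plus the fitted process- and
#' observation-noise functions.
#'
#' @param x A `treecover_model`.
#' @param groups Keys of groups to draw (default: up to 8, evenly spaced).
#' @param ... Unused.
#' @export
plot.treecover_model <- function(x, groups = NULL, ...) {
  keys <- groups %||% names(x$change)[unique(round(seq(1, length(x$change),
                                                       length.out = min(8, length(x$change)))))]
  xs <- seq(0, 100, by = 0.5)
  old <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  cols <- grDevices::hcl.colors(length(keys), "Zissou 1")
  ys <- lapply(keys, function(kk) predict(x$change[[kk]], xs))
  graphics::plot(NA, xlim = c(0, 100), ylim = range(unlist(ys)),
                 xlab = "tree cover (%)", ylab = "change (% / y)",
                 main = "fitted drift f(X)")
  graphics::abline(h = 0, lty = 2)
  for (i in seq_along(keys)) {
    graphics::lines(xs, ys[[i]], col = cols[i])
    eq <- find_equilibria(x$change[[keys[i]]])
    if (nrow(eq))
      graphics::points(eq$root, rep(0, nrow(eq)), col = cols[i],
                       pch = ifelse(eq$stability == "stable", 19, 1))
  }
  graphics::legend("topright", legend = keys, col = cols, lty = 1, cex = 0.6)
  graphics::plot(xs, x$noise$process(xs), type = "l", ylim =
                   range(0, x$noise$process(xs), x$noise$observation(xs)),
                 xlab = "tree cover (%)", ylab = "noise amplitude",
                 main = "noise g(X), h(X)")
  graphics::lines(xs, x$noise$observation(xs), lty = 2)
  graphics::legend("topright", legend = c("process g", "observation h"),
                   lty = c(1, 2), cex = 0.8)
  invisible(x)
}
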