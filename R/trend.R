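#' Theil-Sen slope of an annual series
#'
#' The median of the slopes between every pair of observations, a robust
#' trend estimate for short, noisy remote-sensing series. Missing values are
#' skipped; pairs at identical time points (zero time difference) are
#' excluded as their slope is undefined.
#'
#' @param cover Numeric cover values (% of plot), possibly with `NA`.
#' @param years Time points matching `cover`; defaults to `0, 1, 2, ...`.
#' @return The annual change in % per year (median of pairwise slopes; for
#'   an even slope count, the midpoint of the two central slopes).
#' @examples
#' theil_sen(c(10, 12, 11, 15))        # 1.5833...
#' theil_sen(c(5, 5, 5))               # 0
#' @export
theil_sen <- function(cover, years = seq_along(cover) - 1) {
  ok <- !is.na(cover) & !is.na(years)
  x <- as.numeric(years[ok]); y <- as.numeric(cover[ok])
  if (length(y) < 2)
    stop_borealstate("theil_sen: need at least 2 non-missing values, got %d", length(y))
  ij <- utils::combn(length(y), 2)
  dx <- x[ij[2, ]] - x[ij[1, ]]
  keep <- dx != 0
  if (!any(keep))
    stop_borealstate("theil_sen: all observation pairs share the same time point")
  stats::median((y[ij[2, ]] - y[ij[1, ]])[keep] / dx[keep])
}

# Per-plot change summary for a panel: initial (first-year) cover and the
# Theil-Sen annual change. Complete panels use a vectorized all-pairs path;
# panels with missing cells fall back to the per-series estimator.
panel_changes <- function(panel) {
  V <- panel_cover(panel)
  yrs <- panel_years(panel)
  if (!anyNA(V)) {
    ij <- utils::combn(ncol(V), 2)
    dx <- yrs[ij[2, ]] - yrs[ij[1, ]]
    slopes <- (V[, ij[2, ], drop = FALSE] - V[, ij[1, ], drop = FALSE]) /
      rep(dx, each = nrow(V))
    change <- apply(slopes, 1, stats::median)
  } else {
    change <- apply(V, 1, function(row) theil_sen(row, yrs))
  }
  out <- data.frame(plot_id = panel$plot_id, mat = panel$mat,
                    x0 = V[, 1], change = change, stringsAsFactors = FALSE)
  for (sc in panel_strata_cols(panel)) out[[sc]] <- panel[[sc]]
  rownames(out) <- NULL
  out
}

# ---- change models -------------------------------------------------------

new_change_model <- function(fit = NULL, fn = NULL, support = c(0, 100),
                             bin = NA_integer_, stratum = NULL, n_fit = NA_integer_,
                             grid = NULL) {
  structure(list(fit = fit, fn = fn, support = support, bin = bin,
                 stratum = stratum, n_fit = n_fit, grid = grid),
            class = "change_model")
}

#' Wrap a plain drift function as a change model
#'
#' Lets hand-specified drifts (for simulation experiments or tests) be used
#' anywhere a fitted change model is accepted.
#'
#' @param fn Function of cover (%) returning change (% per year).
#' @param support Cover interval the function is considered native on.
#' @return A `change_model`.
#' @export
as_change_model <- function(fn, support = c(0, 100)) {
  stopifnot(is.function(fn))
  new_change_model(fn = fn, support = support)
}

#' Evaluate a change model
#'
#' Inside the fitted cover support the penalized spline is evaluated
#' directly; outside, the smooth is continued linearly from the boundary
#' value and boundary slope, so that warming-driven bin switches can move
#' plots beyond the cover range a bin's model was fitted on.
#'
#' @param object A `change_model`.
#' @param cover Numeric cover values.
#' @param ... Unused.
#' @return Expected annual change (% per year) at `cover`.
#' @export
predict.change_model <- function(object, cover, ...) {
  x <- as.numeric(cover)
  if (!is.null(object$fn)) return(object$fn(x))
  lo <- object$support[1]; hi <- object$support[2]
  xc <- pmin(pmax(x, lo), hi)
  y <- as.numeric(mgcv::predict.gam(object$fit, newdata = data.frame(x0 = xc)))
  eps <- 1e-3
  if (any(x < lo)) {
    d_lo <- diff(as.numeric(mgcv::predict.gam(object$fit,
             newdata = data.frame(x0 = c(lo, lo + eps))))) / eps
    y[x < lo] <- y[x < lo] + d_lo * (x[x < lo] - lo)
  }
  if (any(x > hi)) {
    d_hi <- diff(as.numeric(mgcv::predict.gam(object$fit,
             newdata = data.frame(x0 = c(hi - eps, hi))))) / eps
    y[x > hi] <- y[x > hi] + d_hi * (x[x > hi] - hi)
  }
  y
}

#' @export
print.change_model <- function(x, ...) {
  src <- if (is.null(x$fn)) sprintf("spline fit, n = %d", x$n_fit) else "function"
  cat(sprintf("Change model (bin %s%s): %s; support [%.1f, %.1f]\n",
              ifelse(is.na(x$bin), "-", x$bin),
              if (length(x$stratum)) paste0(", ", paste(x$stratum, collapse = "/")) else "",
              src, x$support[1], x$support[2]))
  invisible(x)
}

# Fast lookup table for simulation: drift evaluated on a fine cover grid.
change_lookup <- function(model, step = 0.1) {
  if (!is.null(model$fn)) return(NULL)  # exact evaluation is cheap
  x <- seq(0, 100, by = step)
  list(x = x, y = predict(model, x))
}

eval_drift_fast <- function(model, lookup, x) {
  if (is.null(lookup)) return(model$fn(x))
  stats::approx(lookup$x, lookup$y, xout = x, rule = 2)$y
}

#' Fit per-bin deterministic change models
#'
#' For each temperature bin (and optional stratum combination), relates the
#' Theil-Sen annual change of each plot to its initial (first-year) cover
#' with a penalized cubic regression spline (basis dimension `k`, smoothness
#' by GCV). The fitted smooth is the deterministic drift `f(X)` of the
#' stochastic cover model.
#'
#' @param panel A `cover_panel`.
#' @param bins A [temperature_bins()] object.
#' @param strata Character vector of panel strata columns to additionally
#'   group by (default none).
#' @param k Spline basis dimension (default 10).
#' @param min_n Minimum plots per group (default 50); smaller groups are
#'   skipped and listed in the result.
#' @param changes Optional precomputed result of the internal change
#'   summary; used by callers that need the per-plot changes too.
#' @return An object of class `change_model_set`: a list of `change_model`s
#'   keyed by `"<bin>"` or `"<bin>|<stratum>"`, with attributes `bins` and
#'   `skipped`.
#' @export
fit_change_model <- function(panel, bins = temperature_bins(), strata = NULL,
                             k = 10, min_n = 50, changes = NULL) {
  if (nrow(panel) == 0) stop_borealstate("fit_change_model: empty panel")
  ch <- changes %||% panel_changes(panel)
  ch$bin <- assign_bin(ch$mat, bins)
  key <- as.character(ch$bin)
  if (!is.null(strata) && length(strata)) {
    missing_cols <- setdiff(strata, names(ch))
    if (length(missing_cols))
      stop_borealstate("fit_change_model: strata column(s) %s not in panel",
                       paste(missing_cols, collapse = ", "))
    key <- paste(key, do.call(paste, c(ch[strata], sep = "/")), sep = "|")
  }
  groups <- split(seq_len(nrow(ch)), key)
  models <- list()
  skipped <- character(0)
  for (gname in names(groups)) {
    idx <- groups[[gname]]
    if (length(idx) < min_n) { skipped <- c(skipped, gname); next }
    d <- ch[idx, , drop = FALSE]
    kk <- min(k, max(3L, length(unique(d$x0)) - 1L))
    fit <- mgcv::gam(change ~ s(x0, bs = "cr", k = kk), data = d, method = "GCV.Cp")
    bin_i <- as.integer(sub("\\|.*$", "", gname))
    stratum <- if (grepl("|", gname, fixed = TRUE)) sub("^[^|]*\\|", "", gname) else NULL
    m <- new_change_model(fit = fit, support = range(d$x0), bin = bin_i,
                          stratum = stratum, n_fit = length(idx))
    m$grid <- data.frame(cover = seq(0, 100, by = 0.5),
                         change = predict(m, seq(0, 100, by = 0.5)))
    models[[gname]] <- m
  }
  if (!length(models))
    stop_borealstate("fit_change_model: every group below min_n = %d (groups: %s)",
                     min_n, paste(skipped, collapse = ", "))
  structure(models, bins = bins, skipped = skipped, strata = strata,
            class = "change_model_set")
}

#' @export
print.change_model_set <- function(x, ...) {
  cat(sprintf("Change model set: %d fitted group(s), %d skipped\n",
              length(x), length(attr(x, "skipped"))))
  invisible(x)
}

# Resolve the model for a bin index, snapping to the nearest fitted bin:
# warming beyond the warmest fitted bin uses the warmest bin's model, and
# symmetrically at the cold end. `stratum` selects within a stratified set.
resolve_bin_model <- function(models, bin, stratum = NULL) {
  keys <- names(models)
  if (!is.null(stratum)) {
    keys <- keys[endsWith(keys, paste0("|", stratum))]
    if (!length(keys))
      stop_borealstate("no fitted models for stratum '%s'", stratum)
  }
  fitted_bins <- as.integer(sub("\\|.*$", "", keys))
  o <- order(fitted_bins)
  fitted_bins <- fitted_bins[o]; keys <- keys[o]
  nb <- length(fitted_bins)
  i <- findInterval(bin, fitted_bins)
  i0 <- pmax(i, 1L)
  lo <- fitted_bins[i0]; hi <- fitted_bins[pmin(i0 + 1L, nb)]
  pick <- ifelse(i < 1L, 1L,
                 ifelse(abs(bin - lo) <= abs(hi - bin), i0, pmin(i0 + 1L, nb)))
  keys[pick]
}
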