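#' Fit a cover-to-biomass model by AIC selection
#'
#' Fits candidate families relating tree cover (%) to aboveground biomass
#' (AGB, t/ha) by least squares on the natural scale and keeps the family
#' with the lowest AIC. All AICs use a common Gaussian likelihood on the
#' natural scale so they are comparable across families (log- and
#' natural-scale AICs are not).
#'
#' Families: `linear` (`b0 + b1*x`), `power` (`alpha * x^beta`),
#' `exponential` (`alpha * exp(beta*x)`). The nonlinear families are started
#' from their exact log-linearizations and refined with [stats::nls()]; a
#' family that fails to converge is dropped with a warning.
#'
#' @param pairs Data frame with columns `cover` (%) and `agb` (t/ha);
#'   at least 10 pairs spanning at least 30 cover-%.
#' @param families Candidate families to fit.
#' @return An object of class `biomass_model`: `family` (selected),
#'   `coefficients`, `aic` (named vector over fitted candidates), `fits`.
#' @examples
#' x <- seq(5, 80, length.out = 40)
#' m <- fit_biomass_model(data.frame(cover = x, agb = 5 * exp(0.04 * x)))
#' m$family   # "exponential"
#' @export
fit_biomass_model <- function(pairs,
                              families = c("linear", "power", "exponential")) {
  stopifnot(all(c("cover", "agb") %in% names(pairs)))
  pairs <- pairs[stats::complete.cases(pairs[c("cover", "agb")]), ]
  n <- nrow(pairs)
  if (n < 10) stop_borealstate("fit_biomass_model: need >= 10 pairs, got %d", n)
  if (diff(range(pairs$cover)) < 30)
    stop_borealstate("fit_biomass_model: cover span %.1f%% < 30%%",
                     diff(range(pairs$cover)))
  gauss_aic <- function(rss, p) n * log(2 * pi * rss / n) + n + 2 * (p + 1)
  fits <- list(); aic <- c()
  for (fam in families) {
    res <- tryCatch({
      if (fam == "linear") {
        fit <- stats::lm(agb ~ cover, data = pairs)
        list(fit = fit, coef = stats::setNames(stats::coef(fit), c("b0", "b1")),
             rss = sum(stats::resid(fit)^2), p = 2)
      } else if (fam == "power") {
        pos <- pairs$cover > 0 & pairs$agb > 0
        if (sum(pos) < 10) stop("too few positive pairs")
        ll <- stats::lm(log(agb) ~ log(cover), data = pairs[pos, ])
        st <- c(alpha = unname(exp(stats::coef(ll)[1])),
                beta = unname(stats::coef(ll)[2]))
        co <- refine_nls(agb ~ alpha * cover^beta, pairs[pos, ], st, "power")
        rss <- sum((pairs$agb - predict_family("power", as.list(co), pairs$cover))^2)
        list(fit = NULL, coef = co, rss = rss, p = 2)
      } else if (fam == "exponential") {
        pos <- pairs$agb > 0
        if (sum(pos) < 10) stop("too few positive pairs")
        ll <- stats::lm(log(agb) ~ cover, data = pairs[pos, ])
        st <- c(alpha = unname(exp(stats::coef(ll)[1])),
                beta = unname(stats::coef(ll)[2]))
        co <- refine_nls(agb ~ alpha * exp(beta * cover), pairs, st, "exponential")
        rss <- sum((pairs$agb - predict_family("exponential", as.list(co), pairs$cover))^2)
        list(fit = NULL, coef = co, rss = rss, p = 2)
      } else stop_borealstate("unknown family '%s'", fam)
    }, error = function(e) {
      warning(sprintf("biomass family '%s' failed to fit: %s", fam,
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (!is.null(res)) {
      fits[[fam]] <- res
      aic[fam] <- gauss_aic(res$rss, res$p)
    }
  }
  if (!length(fits))
    stop_borealstate("fit_biomass_model: no candidate family could be fitted")
  sel <- names(which.min(aic))
  structure(list(family = sel, coefficients = fits[[sel]]$coef,
                 aic = aic, fits = fits, n = n),
            class = "biomass_model")
}

# Least-squares refinement of the log-linearized start. On exact
# (zero-residual) data nls's relative-offset criterion cannot be met even
# though the start is the solution; in that case the start is kept.
refine_nls <- function(formula, data, start, fam) {
  fit <- tryCatch(stats::nls(formula, data = data, start = as.list(start),
                             control = stats::nls.control(maxiter = 200)),
                  error = function(e) e)
  if (!inherits(fit, "error")) return(stats::coef(fit))
  resp <- all.vars(formula)[1]
  env <- c(as.list(data), as.list(start))
  rss0 <- sum((data[[resp]] - eval(formula[[3]], env))^2)
  tss <- sum((data[[resp]] - mean(data[[resp]]))^2)
  if (rss0 <= 1e-8 * max(tss, .Machine$double.eps)) return(start)
  stop(conditionMessage(fit))
}

predict_family <- function(family, coef, cover) {
  switch(family,
    linear      = coef[["b0"]] + coef[["b1"]] * cover,
    power       = coef[["alpha"]] * cover^coef[["beta"]],
    exponential = coef[["alpha"]] * exp(coef[["beta"]] * cover),
    stop_borealstate("unknown family '%s'", family))
}

#' @rdname fit_biomass_model
#' @param object A `biomass_model`.
#' @param cover Cover values (%).
#' @param ... Unused.
#' @return `predict.biomass_model()`: AGB predictions (t/ha), floored at 0.
#' @export
predict.biomass_model <- function(object, cover, ...) {
  pmax(0, unname(predict_family(object$family, object$coefficients,
                                as.numeric(cover))))
}

#' @export
print.biomass_model <- function(x, ...) {
  cat(sprintf("Biomass model: %s (AIC %.1f), n = %d\n", x$family,
              x$aic[x$family], x$n))
  cat("  coefficients:", paste(sprintf("%s = %.4g", names(x$coefficients),
                                       x$coefficients), collapse = ", "), "\n")
  cat("  candidate AICs:", paste(sprintf("%s %.1f", names(x$aic), x$aic),
                                 collapse = ", "), "\n")
  invisible(x)
}

#' Aggregate simulated cover change into biomass change
#'
#' Converts start- and end-snapshot *latent* covers (observation noise is a
#' measurement artifact, not mass) to AGB per plot, then aggregates per
#' temperature bin: mean AGB (t/ha) at start and end, relative change (%),
#' and total change in tonnes (`(mean_end - mean_start) * area`). Bins are
#' taken from the ensemble's initial bin assignment.
#'
#' @param ens A `trajectory_ensemble`.
#' @param model A `biomass_model`.
#' @param areas Named numeric: hectares per bin (names = bin indices), or a
#'   single number used for every bin.
#' @param t_start,t_end Snapshot times (defaults: first and last stored).
#' @return Data frame of class `biomass_change_table` (one row per bin:
#'   `bin`, `n_plots`, `area_ha`, `agb_start`, `agb_end`, `rel_change_pct`,
#'   `total_change_t`) with attribute `grand_total_t`.
#' @export
biomass_change <- function(ens, model, areas, t_start = NULL, t_end = NULL) {
  stopifnot(inherits(ens, "trajectory_ensemble"), inherits(model, "biomass_model"))
  t_start <- t_start %||% ens$time[1]
  t_end <- t_end %||% ens$time[length(ens$time)]
  x0 <- ensemble_snapshot(ens, t_start, "latent")
  x1 <- ensemble_snapshot(ens, t_end, "latent")
  bin <- ens$bin_path[, 1]
  ub <- sort(unique(bin))
  if (length(areas) == 1 && is.null(names(areas)))
    areas <- stats::setNames(rep(areas, length(ub)), ub)
  missing_a <- setdiff(as.character(ub), names(areas))
  if (length(missing_a))
    stop_borealstate("biomass_change: no area for bin(s) %s",
                     paste(missing_a, collapse = ", "))
  rows <- lapply(ub, function(b) {
    sel <- bin == b
    a0 <- mean(predict(model, x0[sel])); a1 <- mean(predict(model, x1[sel]))
    area <- areas[[as.character(b)]]
    data.frame(bin = b, n_plots = sum(sel), area_ha = area,
               agb_start = a0, agb_end = a1,
               rel_change_pct = if (a0 > 0) (a1 - a0) / a0 * 100 else NA_real_,
               total_change_t = (a1 - a0) * area)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, grand_total_t = sum(out$total_change_t),
            class = c("biomass_change_table", "data.frame"))
}
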