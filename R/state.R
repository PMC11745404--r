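#' Equilibria of a drift function
#'
#' Locates zeros of the drift on \[`lower`, `upper`\]: sign changes on a fine
#' grid are refined by bisection, and each root is classified by its local
#' slope (negative slope = stable attractor, positive = unstable repeller).
#' Grid zeros without a sign change are reported as tangential. Boundaries
#' get special treatment, since cover is confined to \[0, 100\]: an endpoint
#' where the drift is numerically zero is classified by its one-sided slope,
#' and an endpoint the drift pushes into (negative drift at the lower bound,
#' positive at the upper) is a stable boundary equilibrium.
#'
#' @param f A `change_model` or plain function of cover.
#' @param lower,upper Search interval (default \[0, 100\]).
#' @param step Grid step in cover % (default 0.1).
#' @param tol Bisection tolerance in cover % (default 1e-4).
#' @param include_boundaries Also report endpoints the drift pushes into
#'   (no zero there, but the state cannot leave) as stable boundary
#'   equilibria (default `FALSE`: only actual zeros of the drift are
#'   returned). Useful for fitted smooths whose value at a boundary
#'   attractor is slightly displaced from zero.
#' @return Data frame of class `equilibrium_set`, sorted by root: columns
#'   `root`, `stability` (`"stable"`/`"unstable"`), `type`
#'   (`"crossing"`/`"boundary"`/`"tangential"`), `slope`.
#' @examples
#' eq <- find_equilibria(function(x) 0.1 * x * (1 - x / 60))
#' eq$root        # 0, 60
#' eq$stability   # unstable, stable
#' @export
find_equilibria <- function(f, lower = 0, upper = 100, step = 0.1, tol = 1e-4,
                            include_boundaries = FALSE) {
  fe <- if (inherits(f, "change_model")) function(x) predict(f, x) else f
  xs <- seq(lower, upper, by = step)
  ys <- fe(xs)
  scale <- max(abs(ys), .Machine$double.eps)
  ztol <- 1e-8 * scale
  h <- step / 10
  slope_at <- function(x) {
    x1 <- max(lower, x - h); x2 <- min(upper, x + h)
    (fe(x2) - fe(x1)) / (x2 - x1)
  }
  roots <- list()
  add <- function(root, type) {
    sl <- slope_at(root)
    roots[[length(roots) + 1L]] <<- data.frame(
      root = root, stability = if (sl < 0) "stable" else "unstable",
      type = type, slope = sl, stringsAsFactors = FALSE)
  }
  # interior sign changes
  sgn <- sign(ys)
  for (i in seq_len(length(xs) - 1L)) {
    if (sgn[i] == 0 || sgn[i + 1] == 0) next
    if (sgn[i] * sgn[i + 1] < 0) {
      r <- stats::uniroot(fe, c(xs[i], xs[i + 1]), tol = tol)$root
      add(r, "crossing")
    }
  }
  # grid zeros without a crossing (tangential or exact grid hits)
  zi <- which(abs(ys) <= ztol)
  for (i in zi) {
    x0 <- xs[i]
    near <- length(roots) && any(abs(vapply(roots, function(r) r$root, 0) - x0) < step)
    if (near) next
    type <- if (i == 1L || i == length(xs)) "boundary" else "tangential"
    add(x0, type)
  }
  # boundaries the drift pushes into (opt-in)
  have <- function(x0) length(roots) &&
    any(abs(vapply(roots, function(r) r$root, 0) - x0) < step)
  if (include_boundaries) {
    if (ys[1] < -ztol && !have(lower))
      roots[[length(roots) + 1L]] <- data.frame(root = lower, stability = "stable",
                                                type = "boundary", slope = slope_at(lower))
    if (ys[length(ys)] > ztol && !have(upper))
      roots[[length(roots) + 1L]] <- data.frame(root = upper, stability = "stable",
                                                type = "boundary", slope = slope_at(upper))
  }
  out <- if (length(roots)) do.call(rbind, roots) else
    data.frame(root = numeric(0), stability = character(0),
               type = character(0), slope = numeric(0))
  out <- out[order(out$root), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("equilibrium_set", "data.frame"))
}

#' Density landscape of cover values
#'
#' Gaussian kernel density on \[0, 100\] with boundary reflection at both
#' ends (probability mass leaking past a boundary is folded back), bandwidth
#' by Silverman's rule unless given, normalized so the trapezoid integral
#' over \[0, 100\] is 1.
#'
#' @param values Numeric cover values (>= 2 distinct observations).
#' @param bw Kernel bandwidth; default `stats::bw.nrd0(values)`.
#' @param grid_step Output grid step in cover % (default 0.1).
#' @param window Optional label for the time window the values cover.
#' @param bin Optional temperature-bin key.
#' @return Data frame of class `density_landscape` with columns `cover`,
#'   `density`, and attributes `bw`, `n`, `window`, `bin`.
#' @export
density_landscape <- function(values, bw = NULL, grid_step = 0.1,
                              window = NULL, bin = NULL) {
  values <- values[!is.na(values)]
  if (length(values) < 2)
    stop_borealstate("density_landscape: need at least 2 values, got %d", length(values))
  bw <- bw %||% stats::bw.nrd0(values)
  g <- seq(0, 100, by = grid_step)
  # exact Gaussian KDE, evaluated in chunks; reflection terms use only the
  # observations close enough to a boundary to contribute
  d <- numeric(length(g))
  chunk <- 5000L
  for (i0 in seq(1, length(values), by = chunk)) {
    v <- values[i0:min(i0 + chunk - 1L, length(values))]
    d <- d + rowSums(stats::dnorm(outer(g, v, "-"), sd = bw))
  }
  near0 <- values[values < 12 * bw]
  if (length(near0)) {
    gl <- g[g < 24 * bw]
    d[seq_along(gl)] <- d[seq_along(gl)] +
      rowSums(stats::dnorm(outer(gl, -near0, "-"), sd = bw))
  }
  near100 <- values[values > 100 - 12 * bw]
  if (length(near100)) {
    sel <- g > 100 - 24 * bw
    d[sel] <- d[sel] + rowSums(stats::dnorm(outer(g[sel], 200 - near100, "-"),
                                            sd = bw))
  }
  d <- d / trapz(g, d)
  structure(data.frame(cover = g, density = d),
            bw = bw, n = length(values), window = window, bin = bin,
            class = c("density_landscape", "data.frame"))
}

#' Modes of a density landscape
#'
#' Local maxima of the density grid kept if their topographic prominence
#' (height above the highest saddle separating them from a higher peak)
#' reaches `min_prominence` times the global peak density; suppresses
#' sampling ripples.
#'
#' @param landscape A [density_landscape()].
#' @param min_prominence Fraction of the global peak (default 0.05).
#' @return Data frame with columns `cover`, `density`, `prominence`, sorted
#'   by descending density.
#' @export
find_modes <- function(landscape, min_prominence = 0.05) {
  d <- landscape$density; x <- landscape$cover
  n <- length(d)
  is_peak <- c(d[1] > d[2], d[2:(n - 1)] > d[1:(n - 2)] & d[2:(n - 1)] >= d[3:n],
               d[n] > d[n - 1])
  pk <- which(is_peak)
  if (!length(pk)) return(data.frame(cover = numeric(0), density = numeric(0),
                                     prominence = numeric(0)))
  prom <- vapply(pk, function(i) {
    h <- d[i]
    higher <- pk[d[pk] > h]
    if (!length(higher)) return(h)  # global peak: prominence = height
    saddle <- -Inf
    for (j in higher) {
      rng <- if (j < i) d[j:i] else d[i:j]
      saddle <- max(saddle, min(rng))
    }
    h - saddle
  }, 0)
  keep <- prom >= min_prominence * max(d)
  out <- data.frame(cover = x[pk[keep]], density = d[pk[keep]],
                    prominence = prom[keep])
  out[order(-out$density), , drop = FALSE]
}

#' Windowed cover densities
#'
#' Pools all plot-year cover values of a panel within each time window
#' (optionally per temperature bin) and estimates a density landscape per
#' window; successive windows visualize how the cover distribution is
#' shifting over the record.
#'
#' @param panel A `cover_panel`.
#' @param windows List of `c(first_year, last_year)` calendar-year ranges;
#'   default four windows of five to six years over 2000--2020.
#' @param bins Optional [temperature_bins()]; if given, densities are
#'   computed per bin (plots grouped by MAT).
#' @param min_values Minimum pooled values per (window, bin) cell; smaller
#'   cells are dropped.
#' @return A list of `density_landscape` objects, named
#'   `"<first>-<last>"` or `"<first>-<last>|bin<i>"`.
#' @export
windowed_densities <- function(panel,
                               windows = list(c(2000, 2004), c(2005, 2009),
                                              c(2010, 2014), c(2015, 2020)),
                               bins = NULL, min_values = 2) {
  yrs <- panel_years(panel)
  V <- panel_cover(panel)
  out <- list()
  groups <- if (is.null(bins)) list(all = seq_len(nrow(V))) else {
    split(seq_len(nrow(V)), assign_bin(panel$mat, bins))
  }
  for (w in windows) {
    sel_y <- which(yrs >= w[1] & yrs <= w[2])
    if (!length(sel_y))
      stop_borealstate("windowed_densities: window %d-%d contains no observed years",
                       w[1], w[2])
    wl <- sprintf("%d-%d", w[1], w[2])
    for (gname in names(groups)) {
      vals <- as.vector(V[groups[[gname]], sel_y, drop = FALSE])
      vals <- vals[!is.na(vals)]
      if (length(vals) < min_values) next
      key <- if (is.null(bins)) wl else sprintf("%s|bin%s", wl, gname)
      out[[key]] <- density_landscape(vals, window = wl,
                                      bin = if (is.null(bins)) NULL else gname)
    }
  }
  if (!length(out))
    stop_borealstate("windowed_densities: no (window, bin) cell had >= %d values",
                     min_values)
  out
}
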