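#' Ground-truth stochastic dynamics for synthetic panels
#'
#' Defines the latent drift-diffusion model a synthetic panel is generated
#' from: a deterministic drift `f(x)` (annual cover change, % per year), a
#' process-noise amplitude `g(x)` (% per sqrt-year) and an observation-noise
#' SD `h(x)` (%), each a function of tree cover `x` in percent.
#'
#' Built-in drifts are the classical population forms used to validate the
#' fitting method:
#' \describe{
#'   \item{logistic}{\code{r*x*(1-x/K)}}
#'   \item{allee (weak)}{\code{r*x*(1-x/K)*x/(x+A)}}
#'   \item{strong_allee}{\code{r*x*(1-x/K)*(x/A-1)}}
#'   \item{custom}{a user-supplied function of cover}
#' }
#'
#' @param drift One of `"logistic"`, `"allee"`, `"strong_allee"`, `"custom"`.
#' @param r Intrinsic rate (per year).
#' @param K Carrying cover in (0, 100].
#' @param A Allee threshold cover; for `strong_allee` requires `0 < A < K`.
#' @param drift_fn Function of cover, required when `drift = "custom"`.
#' @param process_noise Constant or function of cover; must be nonnegative on
#'   \[0, 100\].
#' @param obs_noise Constant or function of cover; must be nonnegative on
#'   \[0, 100\].
#' @return An object of class `ground_truth`.
#' @examples
#' gt <- ground_truth("logistic", r = 0.3, K = 60, process_noise = 2)
#' drift_eval(gt, c(0, 30, 60))
#' @export
ground_truth <- function(drift = c("logistic", "allee", "strong_allee", "custom"),
                         r = 0.3, K = 60, A = 20, drift_fn = NULL,
                         process_noise = 2, obs_noise = 0) {
  drift <- match.arg(drift)
  if (K <= 0 || K > 100)
    stop_borealstate("ground_truth: K must lie in (0, 100], got %g", K)
  if (drift == "strong_allee" && !(A > 0 && A < K))
    stop_borealstate("ground_truth: strong_allee needs 0 < A < K (A=%g, K=%g)", A, K)
  if (drift == "custom" && !is.function(drift_fn))
    stop_borealstate("ground_truth: drift = \"custom\" requires a drift_fn function")
  as_fn <- function(v, name) {
    fn <- if (is.function(v)) v else {
      force(v)
      function(x) rep_len(v, length(x))
    }
    probe <- fn(seq(0, 100, by = 5))
    if (any(probe < 0))
      stop_borealstate("ground_truth: %s must be nonnegative on [0, 100]", name)
    fn
  }
  structure(list(drift_name = drift,
                 drift_params = list(r = r, K = K, A = A),
                 drift_fn = drift_fn,
                 process_noise = as_fn(process_noise, "process_noise"),
                 obs_noise = as_fn(obs_noise, "obs_noise")),
            class = "ground_truth")
}

# Drift formulas, vectorized over cover and over parameters (used by the
# MAT-gradient scheme where r and K vary by plot).
drift_formula <- function(name, x, r, K, A, drift_fn = NULL) {
  switch(name,
    logistic     = r * x * (1 - x / K),
    allee        = r * x * (1 - x / K) * x / (x + A),
    strong_allee = r * x * (1 - x / K) * (x / A - 1),
    custom       = drift_fn(x),
    stop_borealstate("unknown drift '%s'", name))
}

#' @rdname ground_truth
#' @param truth A `ground_truth` object.
#' @param cover Numeric cover values in \[0, 100\].
#' @return `drift_eval()`: drift values (% per year).
#' @export
drift_eval <- function(truth, cover) {
  stopifnot(inherits(truth, "ground_truth"))
  if (any(cover < 0 | cover > 100, na.rm = TRUE))
    stop_borealstate("drift_eval: cover outside [0, 100]")
  p <- truth$drift_params
  drift_formula(truth$drift_name, cover, p$r, p$K, p$A, truth$drift_fn)
}

#' Configuration for synthetic panel generation
#'
#' @param n_plots Number of plots (>= 1).
#' @param years Number of annual observations per plot (>= 2; default 21,
#'   emulating a 2000--2020 record).
#' @param start_year First calendar year (default 2000).
#' @param dt_internal Euler--Maruyama substep in years, in (0, 1]; default
#'   0.1, the same step used for forward projection so that generation and
#'   inference share a discretization-error scale.
#' @param mat_range MAT range (degrees Celsius) plots are drawn from,
#'   uniformly.
#' @param seed Integer seed; generation is fully reproducible from it.
#' @param init Either `"uniform"` (initial cover uniform on `init_range`) or
#'   a numeric vector of initial covers recycled over plots.
#' @param init_range Range for uniform initial cover.
#' @param mat_gradient Optional named list mapping drift parameters to
#'   `c(cold_value, warm_value)`; each plot's parameter is linearly
#'   interpolated over `mat_range` from its MAT, producing e.g. the
#'   warm-dense / cold-sparse pattern of real boreal cover. Only `r`, `K`,
#'   `A` may appear.
#' @param strata Optional named list of category label vectors (e.g.
#'   `list(region = c("NAm", "Eurasia"))`); labels are assigned uniformly at
#'   random per plot.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_plots, years = 21, start_year = 2000,
                             dt_internal = 0.1, mat_range = c(-14, 6),
                             seed = 1L, init = "uniform",
                             init_range = c(0, 100), mat_gradient = NULL,
                             strata = NULL) {
  if (n_plots < 1) stop_borealstate("synthetic_config: n_plots must be >= 1")
  if (years < 2) stop_borealstate("synthetic_config: years must be >= 2")
  if (!(dt_internal > 0 && dt_internal <= 1))
    stop_borealstate("synthetic_config: dt_internal must lie in (0, 1]")
  if (!is.null(mat_gradient) &&
      !all(names(mat_gradient) %in% c("r", "K", "A")))
    stop_borealstate("synthetic_config: mat_gradient names must be among r, K, A")
  structure(list(n_plots = as.integer(n_plots), years = as.integer(years),
                 start_year = as.integer(start_year),
                 dt_internal = dt_internal, mat_range = mat_range,
                 seed = as.integer(seed), init = init,
                 init_range = init_range, mat_gradient = mat_gradient,
                 strata = strata),
            class = "synthetic_config")
}

#' Generate a synthetic plot panel from known dynamics
#'
#' Simulates each plot's latent cover with the Euler--Maruyama scheme
#' `X(t+dt) = X(t) + dt*f(X) + sqrt(dt)*g(X)*xi` at substep `dt_internal`,
#' samples the path annually, then superimposes observation noise
#' `h(X) * B` with `B` standard normal. Both latent and observed values are
#' clipped to \[0, 100\] (cover is a bounded percentage).
#'
#' @param truth A [ground_truth()] model.
#' @param cfg A [synthetic_config()].
#' @param latent If `TRUE`, attach the noise-free latent panel as attribute
#'   `"latent"` (used by validation tests).
#' @return A `cover_panel` data frame: columns `plot_id`, `mat`, any strata
#'   columns, then one `tc_<year>` column per year.
#' @examples
#' gt <- ground_truth("logistic", r = 0.3, K = 60, process_noise = 2)
#' p <- generate_panel(gt, synthetic_config(n_plots = 50, seed = 7))
#' dim(p)
#' @export
generate_panel <- function(truth, cfg, latent = FALSE) {
  stopifnot(inherits(truth, "ground_truth"), inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  n <- cfg$n_plots
  mat <- stats::runif(n, cfg$mat_range[1], cfg$mat_range[2])

  strata_df <- NULL
  if (!is.null(cfg$strata)) {
    strata_df <- as.data.frame(lapply(cfg$strata, function(lv)
      sample(lv, n, replace = TRUE)), stringsAsFactors = FALSE)
  }

  # Per-plot drift parameters, optionally modulated along the MAT gradient.
  p <- truth$drift_params
  par_r <- rep_len(p$r, n); par_K <- rep_len(p$K, n); par_A <- rep_len(p$A, n)
  if (!is.null(cfg$mat_gradient)) {
    w <- (mat - cfg$mat_range[1]) / diff(cfg$mat_range)
    g <- cfg$mat_gradient
    if (!is.null(g$r)) par_r <- g$r[1] + w * diff(g$r)
    if (!is.null(g$K)) par_K <- g$K[1] + w * diff(g$K)
    if (!is.null(g$A)) par_A <- g$A[1] + w * diff(g$A)
  }

  x <- if (identical(cfg$init, "uniform")) {
    stats::runif(n, cfg$init_range[1], cfg$init_range[2])
  } else {
    clip_cover(rep_len(as.numeric(cfg$init), n))
  }

  nsub <- max(1L, as.integer(round(1 / cfg$dt_internal)))
  dt <- 1 / nsub
  lat <- matrix(NA_real_, n, cfg$years)
  lat[, 1] <- x
  for (yr in seq_len(cfg$years - 1L)) {
    for (s in seq_len(nsub)) {
      f <- drift_formula(truth$drift_name, x, par_r, par_K, par_A, truth$drift_fn)
      x <- clip_cover(x + dt * f + sqrt(dt) * truth$process_noise(x) * stats::rnorm(n))
    }
    lat[, yr + 1L] <- x
  }
  obs <- clip_cover(lat + truth$obs_noise(lat) * stats::rnorm(length(lat)))

  years <- cfg$start_year + seq_len(cfg$years) - 1L
  out <- cover_panel(plot_id = sprintf("p%06d", seq_len(n)), mat = mat,
                     cover = obs, years = years, strata = strata_df)
  if (latent) {
    attr(out, "latent") <- cover_panel(plot_id = sprintf("p%06d", seq_len(n)),
                                       mat = mat, cover = lat, years = years,
                                       strata = strata_df)
  }
  out
}

#' Assemble a cover panel from components
#'
#' @param plot_id Character plot identifiers.
#' @param mat Numeric MAT per plot.
#' @param cover Numeric matrix, plots by years, values in \[0, 100\] or NA.
#' @param years Strictly increasing integer calendar years, one per column.
#' @param strata Optional data frame of categorical columns.
#' @return A `cover_panel` data frame (wide: `tc_<year>` columns).
#' @export
cover_panel <- function(plot_id, mat, cover, years, strata = NULL) {
  cover <- as.matrix(cover)
  if (length(years) != ncol(cover))
    stop_borealstate("cover_panel: %d years but %d cover columns",
                     length(years), ncol(cover))
  if (any(diff(years) <= 0))
    stop_borealstate("cover_panel: years must be strictly increasing")
  if (any(cover < 0 | cover > 100, na.rm = TRUE))
    stop_borealstate("cover_panel: cover values outside [0, 100]")
  colnames(cover) <- paste0("tc_", years)
  out <- data.frame(plot_id = as.character(plot_id), mat = as.numeric(mat),
                    stringsAsFactors = FALSE)
  if (!is.null(strata) && ncol(as.data.frame(strata)) > 0)
    out <- cbind(out, as.data.frame(strata, stringsAsFactors = FALSE))
  out <- cbind(out, as.data.frame(cover))
  rownames(out) <- NULL
  structure(out, years = as.integer(years),
            strata_cols = if (is.null(strata)) character(0) else names(as.data.frame(strata)),
            class = c("cover_panel", "data.frame"))
}

#' @rdname cover_panel
#' @param panel A `cover_panel`.
#' @return `panel_years()`: the calendar years; `panel_cover()`: the plots ×
#'   years cover matrix.
#' @export
panel_years <- function(panel) {
  yrs <- attr(panel, "years")
  if (is.null(yrs)) {
    cols <- grep("^tc_", names(panel), value = TRUE)
    yrs <- as.integer(sub("^tc_", "", cols))
  }
  yrs
}

#' @rdname cover_panel
#' @export
panel_cover <- function(panel) {
  cols <- paste0("tc_", panel_years(panel))
  m <- as.matrix(panel[, cols, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- panel$plot_id
  m
}

#' @rdname cover_panel
#' @export
panel_strata_cols <- function(panel) attr(panel, "strata_cols") %||% character(0)

#' Linear warming trajectory
#'
#' A synthetic stand-in for climate-model MAT projections: MAT offsets per
#' simulated year, by default a linear ramp.
#'
#' @param start_mat Baseline MAT (degrees Celsius) at year offset 0.
#' @param rate Warming rate in degrees Celsius per year.
#' @param years Number of years to tabulate (>= 1).
#' @return Data frame with columns `year` (offset 0..years), `mat`
#'   (absolute MAT for a plot starting at `start_mat`) and `dmat` (offset
#'   applied to any plot's baseline MAT).
#' @examples
#' w <- generate_warming(-0.2, 0.04, 10)
#' w$mat[w$year == 5]   # 0.0
#' @export
generate_warming <- function(start_mat, rate, years) {
  if (years < 1) stop_borealstate("generate_warming: years must be >= 1")
  year <- 0:years
  data.frame(year = year, mat = start_mat + rate * year, dmat = rate * year)
}
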