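#' Simulation configuration for forward projection
#'
#' @param dt Integration step in years (default 0.1).
#' @param steps Number of Euler--Maruyama steps (default 990, the published
#'   horizon for year 2100 from year 2000; use 1000 for a full 100 years at
#'   `dt = 0.1`).
#' @param seed Integer seed; required for reproducibility.
#' @param record_every Steps between stored snapshots (default `1/dt`,
#'   i.e. annual).
#' @param boundary `"clip"` (default) or `"reflect"` at 0 and 100.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(dt = 0.1, steps = 990, seed = 1L,
                              record_every = NULL, boundary = c("clip", "reflect")) {
  if (dt <= 0) stop_borealstate("simulation_config: dt must be > 0")
  boundary <- match.arg(boundary)
  record_every <- as.integer(record_every %||% max(1, round(1 / dt)))
  structure(list(dt = dt, steps = as.integer(steps), seed = as.integer(seed),
                 record_every = record_every, boundary = boundary),
            class = "simulation_config")
}

#' One Euler--Maruyama step
#'
#' `x + dt*f(x) + sqrt(dt)*g(x)*draw`, bounded to \[0, 100\].
#'
#' @param x Cover values in \[0, 100\].
#' @param f A `change_model` (or any object with a `predict` method over
#'   cover) giving the drift in % per year.
#' @param g A `noise_model` (its `process` element is used) or a function of
#'   cover giving the diffusion amplitude.
#' @param dt Step in years.
#' @param draw Standard-normal draws, one per element of `x`.
#' @param boundary `"clip"` or `"reflect"`.
#' @return Updated cover values.
#' @export
em_step <- function(x, f, g, dt, draw, boundary = "clip") {
  fv <- if (inherits(f, "change_model")) predict(f, x) else f(x)
  gv <- if (inherits(g, "noise_model")) g$process(x) else g(x)
  xn <- x + dt * fv + sqrt(dt) * gv * draw
  if (boundary == "reflect") reflect_cover(xn) else clip_cover(xn)
}

#' Project a tree-cover ensemble forward
#'
#' Integrates every plot with the drift of its current temperature bin and
#' the shared process-noise function, by Euler--Maruyama. With a warming
#' trajectory, each plot's bin is re-resolved once per simulated year from
#' its warmed MAT; plots warming beyond the warmest fitted bin keep using
#' the warmest bin's model (and symmetrically at the cold end).
#'
#' @param init Data frame with columns `cover` (initial cover %, typically
#'   the first panel year) and `mat` (MAT, degrees Celsius); optional
#'   `plot_id`.
#' @param models A `change_model_set` (per-bin drifts), or a single
#'   `change_model` applied to every plot.
#' @param noise A `noise_model`; its `process` element drives the diffusion.
#'   Observation noise is *not* added here (see
#'   [add_observation_noise()]) -- it is a measurement artifact superimposed
#'   on stored snapshots, never fed back into the dynamics.
#' @param cfg A [simulation_config()].
#' @param bins [temperature_bins()] used for bin assignment.
#' @param warming Optional data frame with columns `year` (offset from the
#'   start, 0-based) and `dmat` (MAT offset added to every plot's baseline
#'   MAT), e.g. from [generate_warming()]. `NULL` keeps bins fixed.
#' @param stratum Optional stratum key selecting models within a stratified
#'   set.
#' @return An object of class `trajectory_ensemble`: `latent` (plots x
#'   snapshots matrix), `observed` (`NULL` until observation noise is
#'   added), `time` (years since start per snapshot), `bin_path` (plots x
#'   simulated years), `config`.
#' @export
simulate_ensemble <- function(init, models, noise, cfg = simulation_config(),
                              bins = temperature_bins(), warming = NULL,
                              stratum = NULL) {
  stopifnot(is.data.frame(init), all(c("cover", "mat") %in% names(init)))
  if (inherits(models, "change_model")) {
    models <- structure(stats::setNames(list(models), "1"),
                        bins = bins, class = "change_model_set")
    bin_of <- function(mat_now) rep(1L, length(mat_now))
  } else {
    stopifnot(inherits(models, "change_model_set"))
    bin_of <- function(mat_now) assign_bin(mat_now, bins)
  }
  n <- nrow(init)
  x <- clip_cover(as.numeric(init$cover))
  lookups <- lapply(models, change_lookup)
  steps_per_year <- max(1L, as.integer(round(1 / cfg$dt)))
  n_years <- as.integer(ceiling(cfg$steps / steps_per_year))

  dmat_at <- function(yr) {
    if (is.null(warming)) return(0)
    stats::approx(warming$year, warming$dmat, xout = yr, rule = 2)$y
  }

  snaps <- seq(0, cfg$steps, by = cfg$record_every)
  latent <- matrix(NA_real_, n, length(snaps))
  latent[, 1] <- x
  bin_path <- matrix(NA_integer_, n, n_years)

  set.seed(cfg$seed)
  key_now <- NULL
  snap_i <- 1L
  for (step in seq_len(cfg$steps)) {
    yr <- (step - 1L) %/% steps_per_year      # simulated year, 0-based
    if (step == 1L || (step - 1L) %% steps_per_year == 0L) {
      b <- bin_of(init$mat + dmat_at(yr))
      key_now <- resolve_bin_model(models, b, stratum)
      bin_path[, yr + 1L] <- b
    }
    draw <- stats::rnorm(n)
    for (kk in unique(key_now)) {
      sel <- key_now == kk
      fv <- eval_drift_fast(models[[kk]], lookups[[kk]], x[sel])
      gv <- noise$process(x[sel])
      xn <- x[sel] + cfg$dt * fv + sqrt(cfg$dt) * gv * draw[sel]
      x[sel] <- if (cfg$boundary == "reflect") reflect_cover(xn) else clip_cover(xn)
    }
    if (snap_i < length(snaps) && step == snaps[snap_i + 1L]) {
      snap_i <- snap_i + 1L
      latent[, snap_i] <- x
    }
  }
  structure(list(latent = latent, observed = NULL,
                 time = snaps * cfg$dt, bin_path = bin_path,
                 plot_id = init$plot_id %||% sprintf("p%06d", seq_len(n)),
                 config = cfg),
            class = "trajectory_ensemble")
}

#' Superimpose observation noise on simulated paths
#'
#' Adds `h(X) * B` (with `B` standard normal, `h` the observation-noise
#' function evaluated at the latent cover) to every stored snapshot, clipped
#' to \[0, 100\]. This reproduces what a satellite sensor would record over
#' the simulated forest and makes model output directly comparable to
#' observed cover distributions.
#'
#' @param ens A `trajectory_ensemble`.
#' @param noise A `noise_model` (its `observation` element is used) or a
#'   function of cover.
#' @param seed Integer seed for the noise draws.
#' @return The ensemble with its `observed` matrix filled.
#' @export
add_observation_noise <- function(ens, noise, seed = 1L) {
  stopifnot(inherits(ens, "trajectory_ensemble"))
  h <- if (inherits(noise, "noise_model")) noise$observation else noise
  set.seed(as.integer(seed))
  ens$observed <- clip_cover(ens$latent +
    h(ens$latent) * stats::rnorm(length(ens$latent)))
  ens
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf("Trajectory ensemble: %d plots, %d snapshots over %.1f years%s\n",
              nrow(x$latent), ncol(x$latent), max(x$time),
              if (is.null(x$observed)) " (latent only)" else " (latent + observed)"))
  invisible(x)
}

#' Extract a snapshot from an ensemble
#'
#' @param ens A `trajectory_ensemble`.
#' @param time Years since the start (must match a stored snapshot).
#' @param what `"latent"` or `"observed"`.
#' @return Numeric cover vector across plots.
#' @export
ensemble_snapshot <- function(ens, time, what = c("latent", "observed")) {
  what <- match.arg(what)
  i <- which(abs(ens$time - time) < 1e-9)
  if (!length(i))
    stop_borealstate("no snapshot at time %.2f (stored: %s)", time,
                     paste(utils::head(ens$time, 20), collapse = ", "))
  m <- ens[[what]]
  if (is.null(m)) stop_borealstate("ensemble has no %s paths", what)
  m[, i[1]]
}
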