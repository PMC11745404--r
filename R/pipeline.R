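#' Validate a pipeline configuration
#'
#' A configuration is a named list (or a YAML file path). Required: `out`
#' (output directory) and an explicit integer seed for every stochastic
#' stage that will run (`seeds$synthesize` when synthesizing,
#' `seeds$simulate` and `seeds$observation` always). Either `panel` (a CSV
#' path) or `synth` (ground-truth + generator settings) must be present.
#' Validation happens before any computation.
#'
#' @param config Named list or YAML file path.
#' @return The normalized configuration list, invisibly classed
#'   `pipeline_config`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop_borealstate("pipeline_config: config must be a list or YAML path")
  if (is.null(config$out)) stop_borealstate("pipeline_config: 'out' directory is required")
  if (is.null(config$panel) && is.null(config$synth))
    stop_borealstate("pipeline_config: need 'panel' (file) or 'synth' (generator settings)")
  if (!is.null(config$panel) && !file.exists(config$panel))
    stop_borealstate("pipeline_config: panel file does not exist: %s", config$panel)
  seeds <- config$seeds
  need_seeds <- c(if (!is.null(config$synth)) "synthesize", "simulate", "observation")
  missing_seeds <- need_seeds[!vapply(need_seeds, function(s)
    is.numeric(seeds[[s]] %||% NULL), logical(1))]
  if (length(missing_seeds))
    stop_borealstate("pipeline_config: missing seed(s) for stage(s): %s",
                     paste(missing_seeds, collapse = ", "))
  if (!is.null(config$biomass$calibration) && !file.exists(config$biomass$calibration))
    stop_borealstate("pipeline_config: calibration file does not exist: %s",
                     config$biomass$calibration)
  structure(config, class = c("pipeline_config", "list"))
}

#' Run the full estimation and projection pipeline
#'
#' Orchestrates: (optional) synthesis -> drift fitting -> noise separation
#' -> forward projection with observation noise -> equilibrium and density
#' analysis -> (optional) biomass change. Every intermediate table is
#' written to the output directory as delimited text, along with
#' `manifest.json` recording the configuration, seeds and package version;
#' reruns with the same configuration are byte-identical.
#'
#' Configuration fields (all optional unless noted):
#' \describe{
#'   \item{out}{output directory (required)}
#'   \item{seeds}{`synthesize`, `simulate`, `observation` (required as
#'     applicable)}
#'   \item{panel}{input panel CSV; or}
#'   \item{synth}{`drift`, `r`, `K`, `A`, `process_noise`, `obs_noise`,
#'     `n_plots`, `years`, `mat_range`, `init_range`, `mat_gradient`}
#'   \item{bins}{`low`, `high`, `width`}
#'   \item{trend}{`k`, `min_n`, `strata`}
#'   \item{noise}{`max_lag`, `min_n`, `method`}
#'   \item{sim}{`dt`, `steps`, `record_every`}
#'   \item{warming}{`rate` (degC/y) and optionally `years`}
#'   \item{windows}{list of `c(first, last)` calendar years}
#'   \item{biomass}{`calibration` (CSV with cover, agb), `area_per_bin`
#'     (ha)}
#' }
#'
#' @param config Named list or YAML path (see [pipeline_config()]).
#' @return Invisibly, a result bundle: the fitted model, the ensemble, the
#'   analysis tables, and the paths written.
#' @export
run_pipeline <- function(config) {
  cfg <- pipeline_config(config)
  out_dir <- cfg$out
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  put <- function(df, name, ...) {
    p <- file.path(out_dir, name)
    write_table_exact(as.data.frame(df), p, ...)
    paths <<- c(paths, p)
    p
  }

  bins <- do.call(temperature_bins, c(cfg$bins %||% list()))

  # --- stage: panel -------------------------------------------------------
  panel <- if (!is.null(cfg$panel)) read_panel(cfg$panel) else {
    s <- cfg$synth
    gt <- ground_truth(drift = s$drift %||% "logistic", r = s$r %||% 0.3,
                       K = s$K %||% 60, A = s$A %||% 20,
                       process_noise = s$process_noise %||% 2,
                       obs_noise = s$obs_noise %||% 0)
    sc <- synthetic_config(n_plots = s$n_plots %||% 2000,
                           years = s$years %||% 21,
                           mat_range = unlist(s$mat_range %||% c(bins$low, bins$high)),
                           init_range = unlist(s$init_range %||% c(0, 100)),
                           mat_gradient = s$mat_gradient,
                           seed = cfg$seeds$synthesize)
    p <- generate_panel(gt, sc)
    write_panel(p, file.path(out_dir, "panel.csv"))
    paths <- c(paths, file.path(out_dir, "panel.csv"))
    p
  }

  # --- stage: fit (drift + noise) ----------------------------------------
  tr <- cfg$trend %||% list()
  no <- cfg$noise %||% list()
  model <- fit_treecover_model(panel, bins = bins,
                               strata = tr$strata,
                               k = tr$k %||% 10, min_n = tr$min_n %||% 50,
                               max_lag = no$max_lag %||% 10,
                               min_n_lag = no$min_n %||% 30,
                               noise_method = no$method %||% "sqrt-sd")
  put(model$changes, "changes.csv")
  write_change_models(model$change, file.path(out_dir, "change_models"))
  if (!is.null(model$noise$coefficients))
    put(model$noise$coefficients, "noise_coefficients.csv")
  xs <- seq(0, 100, by = 0.5)
  put(data.frame(cover = xs, process = model$noise$process(xs),
                 observation = model$noise$observation(xs)), "noise_grid.csv")
  put(coef(model), "equilibria.csv")

  # --- stage: project -----------------------------------------------------
  sim <- cfg$sim %||% list()
  warming <- NULL
  if (!is.null(cfg$warming)) {
    horizon <- ceiling((sim$steps %||% 990) * (sim$dt %||% 0.1))
    warming <- generate_warming(0, cfg$warming$rate,
                                cfg$warming$years %||% horizon)
  }
  ens <- simulate.treecover_model(model, seed = cfg$seeds$simulate,
                                  steps = sim$steps %||% 990,
                                  dt = sim$dt %||% 0.1,
                                  record_every = sim$record_every,
                                  warming = warming, observation = FALSE)
  ens <- add_observation_noise(ens, model$noise, seed = cfg$seeds$observation)
  write_ensemble(ens, file.path(out_dir, "ensemble.csv"))
  paths <- c(paths, file.path(out_dir, "ensemble.csv"))

  # --- stage: analyze -----------------------------------------------------
  t_end <- ens$time[length(ens$time)]
  d_start <- density_landscape(ensemble_snapshot(ens, 0), window = "start")
  d_end_lat <- density_landscape(ensemble_snapshot(ens, t_end), window = "end latent")
  d_end_obs <- density_landscape(ensemble_snapshot(ens, t_end, "observed"),
                                 window = "end observed")
  put(rbind(cbind(which_density = "start", d_start),
            cbind(which_density = "end_latent", d_end_lat),
            cbind(which_density = "end_observed", d_end_obs)), "densities.csv")
  wd <- windowed_densities(panel, windows = lapply(cfg$windows %||%
          list(c(2000, 2004), c(2005, 2009), c(2010, 2014), c(2015, 2020)),
          unlist))
  put(do.call(rbind, lapply(names(wd), function(k)
    cbind(window = k, as.data.frame(wd[[k]])))), "windowed_densities.csv")
  modes <- find_modes(d_end_obs)
  put(modes, "modes_end_observed.csv")

  # --- stage: biomass -----------------------------------------------------
  biomass_tab <- NULL
  if (!is.null(cfg$biomass)) {
    pairs <- utils::read.csv(cfg$biomass$calibration, comment.char = "#")
    bm <- fit_biomass_model(pairs)
    biomass_tab <- biomass_change(ens, bm, areas = cfg$biomass$area_per_bin %||% 1)
    put(biomass_tab, "biomass_change.csv")
  }

  manifest <- list(package = "borealstate",
                   version = as.character(utils::packageVersion("borealstate")),
                   config = unclass(cfg),
                   config_hash = config_hash(cfg),
                   seeds = cfg$seeds,
                   n_plots = nrow(panel),
                   files = basename(paths))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(model = model, ensemble = ens, panel = panel,
                 densities = list(start = d_start, end_latent = d_end_lat,
                                  end_observed = d_end_obs),
                 windowed = wd, modes = modes, biomass = biomass_tab,
                 paths = c(paths, file.path(out_dir, "manifest.json"))))
}

# Deterministic fingerprint of a configuration (polynomial rolling hash over
# its deparsed form); recorded in the run manifest.
config_hash <- function(cfg) {
  bytes <- utf8ToInt(paste(deparse(unclass(cfg)), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
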