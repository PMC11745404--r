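# Delimited-text interchange: comma-separated, UTF-8, '.' decimal. Numeric
# columns are written with 17 significant digits so every value round-trips
# exactly through the package's own readers.

fmt_num <- function(x) {
  out <- formatC(x, digits = 17, format = "g", width = 1)
  out[is.na(x)] <- "NA"
  trimws(out)
}

write_table_exact <- function(df, path, header_lines = character(0)) {
  out <- df
  for (j in seq_along(out)) if (is.numeric(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.table(out, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_header_meta <- function(path) {
  lines <- readLines(path, n = 50, encoding = "UTF-8")
  meta_lines <- grep("^# ", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^# ", "", ml)
    key <- sub(":.*$", "", kv)
    meta[[trimws(key)]] <- trimws(sub("^[^:]*:", "", kv))
  }
  meta
}

#' Read and write cover panels
#'
#' Panels are stored wide: `plot_id`, `mat`, any categorical strata
#' columns, then one `tc_<year>` column per year. Values are validated on
#' read: cover must be numeric and within \[0, 100\] (missing cells allowed),
#' and errors name the offending row.
#'
#' @param path File path.
#' @return `read_panel()`: a `cover_panel`.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop_borealstate("read_panel: no such file: %s", path)
  if (file.size(path) == 0) stop_borealstate("read_panel: empty panel file: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                        colClasses = "character")
  if (nrow(df) == 0) stop_borealstate("read_panel: panel has a header but no rows: %s", path)
  need <- c("plot_id", "mat")
  if (!all(need %in% names(df)))
    stop_borealstate("read_panel: malformed header, need columns %s",
                     paste(need, collapse = ", "))
  tc_cols <- grep("^tc_[0-9]+$", names(df), value = TRUE)
  if (!length(tc_cols))
    stop_borealstate("read_panel: malformed header, no tc_<year> columns")
  years <- as.integer(sub("^tc_", "", tc_cols))
  o <- order(years)
  tc_cols <- tc_cols[o]; years <- years[o]
  cover <- matrix(NA_real_, nrow(df), length(tc_cols))
  for (j in seq_along(tc_cols)) {
    raw <- df[[tc_cols[j]]]
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & raw != "" & raw != "NA" & is.na(v))
    if (length(bad))
      stop_borealstate("read_panel: non-numeric cover '%s' in column %s, row %d",
                       raw[bad[1]], tc_cols[j], bad[1])
    out_of_range <- which(!is.na(v) & (v < 0 | v > 100))
    if (length(out_of_range))
      stop_borealstate("read_panel: cover %g outside [0, 100] in column %s, row %d",
                       v[out_of_range[1]], tc_cols[j], out_of_range[1])
    cover[, j] <- v
  }
  mat <- suppressWarnings(as.numeric(df$mat))
  if (anyNA(mat))
    stop_borealstate("read_panel: non-numeric mat in row %d", which(is.na(mat))[1])
  strata_cols <- setdiff(names(df), c("plot_id", "mat", tc_cols))
  strata <- if (length(strata_cols)) df[strata_cols] else NULL
  cover_panel(plot_id = df$plot_id, mat = mat, cover = cover, years = years,
              strata = strata)
}

#' @rdname read_panel
#' @param panel A `cover_panel`.
#' @export
write_panel <- function(panel, path) {
  write_table_exact(as.data.frame(panel), path)
}

#' Read and write fitted change models as grids
#'
#' Each model is serialized as its drift evaluated on the cover grid
#' 0--100 in steps of 0.5, with a metadata header (bin, stratum, support,
#' n_fit). Reading returns grid-backed models (linear interpolation between
#' grid points) that reproduce the grid exactly.
#'
#' @param models A `change_model_set`.
#' @param dir Directory for the per-model CSV files.
#' @export
write_change_models <- function(models, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bins <- attr(models, "bins")
  for (key in names(models)) {
    m <- models[[key]]
    hdr <- c(sprintf("bin: %d", m$bin),
             sprintf("stratum: %s", m$stratum %||% ""),
             sprintf("support: %s %s", fmt_num(m$support[1]), fmt_num(m$support[2])),
             sprintf("n_fit: %d", m$n_fit),
             sprintf("bins: %s %s %s", fmt_num(bins$low), fmt_num(bins$high),
                     fmt_num(bins$width)))
    grid <- m$grid %||% data.frame(cover = seq(0, 100, by = 0.5),
                                   change = predict(m, seq(0, 100, by = 0.5)))
    write_table_exact(grid, file.path(dir, paste0("change_", gsub("[|/]", "_", key), ".csv")),
                      header_lines = hdr)
  }
  invisible(dir)
}

#' @rdname write_change_models
#' @return `read_change_models()`: a `change_model_set` of grid-backed
#'   models.
#' @export
read_change_models <- function(dir) {
  files <- list.files(dir, pattern = "^change_.*\\.csv$", full.names = TRUE)
  if (!length(files)) stop_borealstate("read_change_models: no model files in %s", dir)
  models <- list()
  bins <- NULL
  for (f in files) {
    meta <- read_header_meta(f)
    grid <- utils::read.csv(f, comment.char = "#")
    sup <- as.numeric(strsplit(meta$support, " +")[[1]])
    fn <- stats::approxfun(grid$cover, grid$change, rule = 2)
    m <- new_change_model(fn = fn, support = sup,
                          bin = as.integer(meta$bin),
                          stratum = if (nzchar(meta$stratum %||% "")) meta$stratum else NULL,
                          n_fit = as.integer(meta$n_fit), grid = grid)
    key <- if (is.null(m$stratum)) as.character(m$bin) else
      paste(m$bin, m$stratum, sep = "|")
    models[[key]] <- m
    if (is.null(bins) && !is.null(meta$bins)) {
      bv <- as.numeric(strsplit(meta$bins, " +")[[1]])
      bins <- temperature_bins(bv[1], bv[2], bv[3])
    }
  }
  structure(models, bins = bins %||% temperature_bins(), skipped = character(0),
            class = "change_model_set")
}

#' Read and write noise tables
#'
#' @param x A `lag_sd_table` or `noise_coefficients` data frame.
#' @param path File path.
#' @export
write_noise_table <- function(x, path) write_table_exact(as.data.frame(x), path)

#' @rdname write_noise_table
#' @param class_out Class to restore on read.
#' @export
read_noise_table <- function(path, class_out = "lag_sd_table") {
  df <- utils::read.csv(path, comment.char = "#")
  structure(df, class = c(class_out, "data.frame"))
}

#' Write ensemble snapshots as a long table
#'
#' Columns: `plot_id`, `time` (years since start), `latent`, `observed`
#' (NA when observation noise has not been added), `bin`.
#'
#' @param ens A `trajectory_ensemble`.
#' @param path File path.
#' @export
write_ensemble <- function(ens, path) {
  n <- nrow(ens$latent); s <- length(ens$time)
  yr_idx <- pmin(floor(ens$time) + 1L, ncol(ens$bin_path))
  df <- data.frame(
    plot_id = rep(ens$plot_id, s),
    time = rep(ens$time, each = n),
    latent = as.vector(ens$latent),
    observed = if (is.null(ens$observed)) NA_real_ else as.vector(ens$observed),
    bin = as.vector(ens$bin_path[, yr_idx]))
  write_table_exact(df, path)
}
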