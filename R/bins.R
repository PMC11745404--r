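#' Temperature bins
#'
#' Half-open mean-annual-temperature (MAT) intervals used as quasi-fixed
#' environments for model fitting and simulation. The defaults span -14 to
#' 6 degrees Celsius in 0.5 degree steps, i.e. 40 bins, the most frequently
#' observed MAT range in the boreal biome.
#'
#' Bin `i` (1-based) covers `[low + (i-1)*width, low + i*width)`. Assignment
#' is a total function: temperatures below `low` fall in the coldest bin and
#' temperatures at or above `high` fall in the warmest bin, mirroring the
#' warmest-bin fallback used when projected warming leaves the fitted range.
#'
#' @param low,high Range limits in degrees Celsius.
#' @param width Bin width in degrees Celsius; `(high - low) / width` must be
#'   a whole number.
#' @return An object of class `temperature_bins` with fields `low`, `high`,
#'   `width` and `n` (bin count).
#' @examples
#' b <- temperature_bins()
#' b$n                      # 40
#' assign_bin(-13.8, b)     # coldest bin
#' assign_bin(6.2, b)       # warmest-bin fallback
#' @export
temperature_bins <- function(low = -14, high = 6, width = 0.5) {
  if (!(high > low) || width <= 0)
    stop_borealstate("temperature_bins: need high > low and width > 0")
  n <- (high - low) / width
  if (abs(n - round(n)) > 1e-8)
    stop_borealstate("temperature_bins: (high - low) / width = %.6f is not an integer", n)
  structure(list(low = low, high = high, width = width, n = as.integer(round(n))),
            class = "temperature_bins")
}

#' @export
print.temperature_bins <- function(x, ...) {
  cat(sprintf("Temperature bins: %d x %.2f degC on [%.1f, %.1f)\n",
              x$n, x$width, x$low, x$high))
  invisible(x)
}

#' @rdname temperature_bins
#' @param mat Numeric vector of mean annual temperatures (degrees Celsius).
#' @param bins A `temperature_bins` object.
#' @return `assign_bin()`: integer bin indices in `1:bins$n`.
#' @export
assign_bin <- function(mat, bins = temperature_bins()) {
  i <- floor((mat - bins$low) / bins$width) + 1L
  pmin(pmax(as.integer(i), 1L), bins$n)
}

#' @rdname temperature_bins
#' @param index Integer bin indices.
#' @return `bin_midpoint()`: bin centre temperatures.
#' @export
bin_midpoint <- function(index, bins = temperature_bins()) {
  bins$low + (index - 0.5) * bins$width
}
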