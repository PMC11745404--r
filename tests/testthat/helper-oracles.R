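# Independent oracles used across tests. These deliberately avoid the
# package's own code paths (plain double loops, quadrature) so they can
# serve as cross-checks.

# All-pairs-median slope, naive double loop.
oracle_theil_sen <- function(values, years = seq_along(values) - 1) {
  slopes <- c()
  n <- length(values)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (is.na(values[i]) || is.na(values[j])) next
      if (years[j] == years[i]) next
      slopes <- c(slopes, (values[j] - values[i]) / (years[j] - years[i]))
    }
  }
  stats::median(slopes)
}

# SD of the stationary density of dX = f dt + g dW on (0, 100),
# p(x) ~ exp(2 * int f/g^2 dx), by direct quadrature for the logistic drift.
oracle_stationary_sd_logistic <- function(r, K, g, step = 0.01) {
  xs <- seq(step, 100 - step, by = step)
  logphi <- 2 * (r / g^2) * (xs^2 / 2 - xs^3 / (3 * K))
  phi <- exp(logphi - max(logphi))
  Z <- sum(phi) * step
  mu <- sum(xs * phi) * step / Z
  sqrt(sum((xs - mu)^2 * phi) * step / Z)
}

# SD of lagged values per (1% cover group, lag), naive loops over a small
# cover matrix.
oracle_lag_sd <- function(V, max_lag, min_n) {
  res <- list()
  for (lag in seq_len(max_lag)) {
    vals <- list()
    for (t in seq_len(ncol(V) - lag)) {
      for (i in seq_len(nrow(V))) {
        g <- as.character(round(V[i, t]))
        vals[[g]] <- c(vals[[g]], V[i, t + lag])
      }
    }
    for (g in names(vals)) {
      if (length(vals[[g]]) >= min_n)
        res[[paste(g, lag)]] <- data.frame(cover_group = as.numeric(g),
                                           lag = lag, sd = stats::sd(vals[[g]]),
                                           n = length(vals[[g]]))
    }
  }
  out <- do.call(rbind, res)
  out <- out[order(out$cover_group, out$lag), ]
  rownames(out) <- NULL
  out
}

# Small helper: a one-bin panel from logistic truth.
make_logistic_panel <- function(n, seed, r = 0.3, K = 60, g = 2, h = 0,
                                init = "uniform", init_range = c(0, 100),
                                years = 21) {
  gt <- ground_truth("logistic", r = r, K = K, process_noise = g, obs_noise = h)
  generate_panel(gt, synthetic_config(n, years = years, seed = seed,
                                      mat_range = c(-1, 1), init = init,
                                      init_range = init_range))
}

one_bin <- temperature_bins(-1, 1, 2)

trapz_ <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
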