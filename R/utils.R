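# Internal helpers shared across modules.

# Cover is a bounded percentage; every state update and every observation is
# constrained to [0, 100].
# (written with which() so matrix dims survive; pmin/pmax would drop them)
clip_cover <- function(x) {
  x[which(x < 0)] <- 0
  x[which(x > 100)] <- 100
  x
}

# One reflection at each boundary; values that overshoot past a full period
# are clipped afterwards (only reachable with pathological step sizes).
reflect_cover <- function(x) {
  x <- ifelse(x < 0, -x, x)
  x <- ifelse(x > 100, 200 - x, x)
  clip_cover(x)
}

# Trapezoid integral on a regular or irregular grid.
trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_borealstate <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}
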