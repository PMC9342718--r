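# Internal helpers shared across modules.

# Canonical age-band labels, in reporting order.
AGE_BANDS <- c("neonatal", "1-59 months")

# Rounding as printed in the source tables: nearest, ties away from zero.
# base::round() rounds half to even, which disagrees on exact .5 boundaries.
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  out <- sign(x) * floor(abs(x) * m + 0.5) / m
  out[is.na(x)] <- NA_real_
  out
}

# Piecewise-linear interpolation on sparse (year, value) anchors, clamped to
# the nearest anchor outside the anchored span. `anchors` is a named numeric
# vector, names are calendar years.
interp_anchors <- function(anchors, year) {
  stopifnot(length(anchors) >= 1L)
  yrs <- as.numeric(names(anchors))
  o <- order(yrs)
  yrs <- yrs[o]
  vals <- as.numeric(anchors)[o]
  if (length(vals) == 1L) {
    return(rep(vals, length(year)))
  }
  stats::approx(yrs, vals, xout = year, rule = 2, ties = "ordered")$y
}

# Run `expr` under a fixed RNG seed without disturbing global random state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Validation failure with a consistent condition class so callers/tests can
# distinguish bad inputs from programming errors.
stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("livesaved_validation_error", "error")))
}

stop_degenerate <- function(...) {
  stop(errorCondition(paste0(...), class = c("livesaved_degenerate_error", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Thousands-separated integer formatting for the human-readable renderer.
format_count <- function(x) {
  formatC(round_half_away(x), format = "d", big.mark = ",")
}
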