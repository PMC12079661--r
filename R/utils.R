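# Internal numeric helpers shared across modules.

#' @keywords internal
assert_scalar_pos <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (strict && x <= 0) stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  if (!strict && x < 0) stop(sprintf("'%s' must be >= 0", name), call. = FALSE)
  invisible(x)
}

#' @keywords internal
assert_finite <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop(sprintf("'%s' must be finite", name), call. = FALSE)
  invisible(x)
}

# Centered moving average; width is forced odd. Edges use shrinking
# (partial) windows so the output has the same length and no NAs.
#' @keywords internal
moving_average <- function(x, width) {
  n <- length(x)
  if (width <= 1L || n == 0L) return(x)
  width <- as.integer(width)
  if (width %% 2L == 0L) width <- width + 1L
  h <- (width - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Rolling mean and SD over a centered window at 1 Hz via cumulative sums.
# Positions whose window is incomplete get NA (they must not compete in
# the minimum-SD selection).
#' @keywords internal
roll_mean_sd <- function(x, width) {
  n <- length(x)
  width <- as.integer(width)
  out <- list(mean = rep(NA_real_, n), sd = rep(NA_real_, n))
  if (n < width) return(out)
  cs1 <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x * x))
  h <- (width - 1L) %/% 2L
  # centered: window [i-h, i+h'] covering exactly `width` samples
  lo <- seq_len(n - width + 1L)
  hi <- lo + width - 1L
  s1 <- cs1[hi + 1L] - cs1[lo]
  s2 <- cs2[hi + 1L] - cs2[lo]
  m <- s1 / width
  v <- pmax((s2 - s1 * s1 / width) / (width - 1L), 0)
  centers <- lo + h
  out$mean[centers] <- m
  out$sd[centers] <- sqrt(v)
  out
}

# First-order recursive update y_t = a*y_{t-1} + (1-a)*target_t with
# y_0 = init, computed in C via stats::filter.
#' @keywords internal
recursive_relax <- function(target, a, init) {
  if (a <= 0) return(target)
  x <- (1 - a) * target
  x[1] <- x[1] + a * init
  as.numeric(stats::filter(x, a, method = "recursive"))
}

# Saturation water-vapor pressure (kPa) over water, Tetens form.
#' @keywords internal
svp_kpa <- function(temp_c) 0.61078 * exp(17.27 * temp_c / (temp_c + 237.3))

# ml of water vapor (STP) per mg of liquid water: 22414 ml/mol / 18020 mg/mol
ML_VAPOR_PER_MG_H2O <- 22414 / 18020

# Derive a stream-specific RNG seed (< 2^31) from a master seed.
#' @keywords internal
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 2654435 + as.numeric(stream) * 97) %%
               2147483629)
}
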