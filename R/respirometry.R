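# Multiplexed flow-through (pull) respirometry corrections: lag alignment,
# instantaneous (z-transform) washout correction, stable-window extraction,
# ambient baselining, water-vapor dilution correction and the gas-exchange
# equations.

#' Chamber time constant
#'
#' `tau = volume / flow`: the time for 63.2% of chamber air to be replaced
#' under perfect mixing. 13 L at 1700 ml min^-1 gives 7.65 min.
#'
#' @param volume_l Chamber volume (liters).
#' @param flow_ml_min Flow rate (ml min^-1).
#' @return Time constant in minutes.
#' @export
time_constant <- function(volume_l, flow_ml_min) {
  assert_scalar_pos(volume_l, "volume_l")
  assert_scalar_pos(flow_ml_min, "flow_ml_min")
  volume_l * 1000 / flow_ml_min
}

#' Fraction of chamber air replaced after a given time
#'
#' `1 - exp(-elapsed/tau)`; one time constant replaces 63.2%.
#'
#' @param elapsed Elapsed time (any unit, same as `tau`).
#' @param tau Time constant.
#' @return Fraction replaced in `[0, 1)`.
#' @export
washout_fraction <- function(elapsed, tau) {
  assert_scalar_pos(tau, "tau")
  if (any(elapsed < 0)) stop("'elapsed' must be >= 0", call. = FALSE)
  1 - exp(-elapsed / tau)
}

#' Align analyzer channels for transport lags
#'
#' Shifts each gas channel earlier by its transport lag (O2 typically 7 s,
#' CO2/H2O 5 s) so all channels line up with the marker; the trailing
#' `max(lag)` samples are dropped.
#'
#' @param trace Gas trace data.frame (`time_s`, `fo2`, `fco2`, `wvp_kpa`,
#'   ... , `marker`).
#' @param lag_o2_s,lag_co2_h2o_s Channel lags (s, non-negative integers).
#' @return The lag-aligned trace (shorter by `max(lag)` rows).
#' @export
lag_align <- function(trace, lag_o2_s = 7, lag_co2_h2o_s = 5) {
  lag_o2_s <- as.integer(lag_o2_s); lag_co2_h2o_s <- as.integer(lag_co2_h2o_s)
  if (lag_o2_s < 0 || lag_co2_h2o_s < 0)
    stop("lags must be >= 0", call. = FALSE)
  n <- nrow(trace)
  m <- max(lag_o2_s, lag_co2_h2o_s)
  if (m >= n) stop("lag exceeds trace length", call. = FALSE)
  keep <- seq_len(n - m)
  out <- trace[keep, , drop = FALSE]
  out$fo2 <- trace$fo2[keep + lag_o2_s]
  out$fco2 <- trace$fco2[keep + lag_co2_h2o_s]
  out$wvp_kpa <- trace$wvp_kpa[keep + lag_co2_h2o_s]
  rownames(out) <- NULL
  out
}

#' Instantaneous (z-transform) washout correction
#'
#' Inverts first-order chamber mixing: for a perfectly mixed chamber with
#' time constant `tau`, the instantaneous input is `F + tau * dF/dt`. The
#' series is first smoothed with a centered moving average, then
#' differentiated by central differences (one-sided at the endpoints).
#' Correcting `F_inf * (1 - exp(-t/tau))` returns `F_inf` up to
#' discretization error.
#'
#' @param x Uniformly sampled series (1 Hz).
#' @param tau_s Chamber time constant (seconds).
#' @param smoothing_window_s Centered moving-average width (s, default 5).
#' @return Corrected series, same length.
#' @export
instantaneous_correct <- function(x, tau_s, smoothing_window_s = 5) {
  assert_scalar_pos(tau_s, "tau_s")
  n <- length(x)
  if (n < smoothing_window_s)
    stop("series shorter than the smoothing window", call. = FALSE)
  xs <- moving_average(x, smoothing_window_s)
  d <- numeric(n)
  if (n >= 3) {
    d[2:(n - 1)] <- (xs[3:n] - xs[1:(n - 2)]) / 2
    d[1] <- xs[2] - xs[1]
    d[n] <- xs[n] - xs[n - 1]
  } else if (n == 2) d[] <- xs[2] - xs[1]
  xs + tau_s * d
}

#' Extract the most stable segment of each sampling window
#'
#' For every dwell (contiguous run of one marker value) the final
#' `stable_final_s` seconds are scanned exhaustively for the contiguous
#' sub-segment covering `stable_frac` of them with the minimum standard
#' deviation of `fo2` (ties broken earliest); channel means over that
#' segment are reported. Runs shorter than `min_run_s` (edge-truncated
#' dwells) are skipped.
#'
#' @param trace Lag-aligned gas trace (may carry extra columns such as a
#'   corrected `fo2`).
#' @param schedule [sampling_schedule()] (dwells must be at least
#'   `stable_final_s`).
#' @param stable_final_s Final window length considered (s, default 30).
#' @param stable_frac Fraction of it retained (default 0.5).
#' @param min_run_s Minimum usable run length (default 45 s, so analyzer
#'   switch transients never reach the scored segment).
#' @return data.frame: `chamber`, `time_s` (dwell end, so points fall on the
#'   multiplexer cadence), `seg_start_s` (start of the selected segment),
#'   `sd_fo2`, and means `fo2`, `fco2`, `wvp_kpa`, `bp_kpa`, `flow_ml_min`.
#' @export
extract_stable_windows <- function(trace, schedule, stable_final_s = 30,
                                   stable_frac = 0.5, min_run_s = 45) {
  if (any(schedule$slots$dwell_s < stable_final_s))
    stop(sprintf("schedule dwell shorter than %d s stable window",
                 stable_final_s), call. = FALSE)
  seg_len <- as.integer(round(stable_frac * stable_final_s))
  r <- rle(trace$marker)
  ends <- cumsum(r$lengths)
  ok <- r$lengths >= max(min_run_s, stable_final_s)
  ends <- ends[ok]; chamb <- r$values[ok]
  nw <- length(ends)
  if (nw == 0L)
    return(data.frame(chamber = integer(), time_s = numeric(),
                      seg_start_s = numeric(),
                      sd_fo2 = numeric(), fo2 = numeric(), fco2 = numeric(),
                      wvp_kpa = numeric(), bp_kpa = numeric(),
                      flow_ml_min = numeric()))

  idx <- outer(ends - stable_final_s + 1L, seq_len(stable_final_s) - 1L, "+")
  row_cumsum <- function(m) {
    for (j in 2:ncol(m)) m[, j] <- m[, j] + m[, j - 1]
    m
  }
  seg_sums <- function(cs, k) {            # sums of segment k..k+seg_len-1
    if (k == 1L) cs[, seg_len] else cs[, k + seg_len - 1L] - cs[, k - 1L]
  }
  M <- matrix(trace$fo2[idx], nw)
  cs1 <- row_cumsum(M)
  cs2 <- row_cumsum(M * M)
  npos <- stable_final_s - seg_len + 1L
  vars <- vapply(seq_len(npos), function(k) {
    s1 <- seg_sums(cs1, k); s2 <- seg_sums(cs2, k)
    pmax((s2 - s1 * s1 / seg_len) / (seg_len - 1L), 0)
  }, numeric(nw))
  vars <- matrix(vars, nw)
  best <- max.col(-vars, ties.method = "first")
  pick <- cbind(seq_len(nw), best)

  seg_mean <- function(col) {
    cs <- row_cumsum(matrix(col[idx], nw))
    lo <- best - 1L
    s <- cs[cbind(seq_len(nw), best + seg_len - 1L)] -
      ifelse(lo >= 1L, cs[cbind(seq_len(nw), pmax(lo, 1L))], 0)
    s / seg_len
  }
  start_t <- trace$time_s[idx[, 1]] + best - 1L
  data.frame(chamber = chamb,
             time_s = trace$time_s[ends],
             seg_start_s = start_t,
             sd_fo2 = sqrt(vars[pick]),
             fo2 = seg_mean(trace$fo2),
             fco2 = seg_mean(trace$fco2),
             wvp_kpa = seg_mean(trace$wvp_kpa),
             bp_kpa = seg_mean(trace$bp_kpa),
             flow_ml_min = seg_mean(trace$flow_ml_min))
}

#' Baseline animal windows against interpolated ambient windows
#'
#' Subtracts, per channel, the linear time-interpolation between the
#' bracketing ambient baseline means from each animal window. Samples before
#' the first (after the last) baseline use the nearest single baseline.
#' Removes any analyzer drift that is affine in time exactly.
#'
#' @param samples Window statistics for animal chambers (from
#'   [extract_stable_windows()], possibly after drying).
#' @param baselines Window statistics for the ambient baseline slots.
#' @param channels Channel columns to difference.
#' @return `samples` with each channel column replaced by a delta column
#'   named `d_<channel>`.
#' @export
baseline_correct <- function(samples, baselines,
                             channels = c("fo2", "fco2", "wvp_kpa")) {
  if (is.null(baselines) || nrow(baselines) == 0L)
    stop("no baseline windows available", call. = FALSE)
  baselines <- baselines[order(baselines$time_s), ]
  bt <- baselines$time_s
  interp <- function(col, t) {
    if (length(bt) == 1L) return(rep(col[1], length(t)))
    stats::approx(bt, col, xout = t, rule = 2, ties = "ordered")$y
  }
  out <- samples
  for (ch in channels) {
    out[[paste0("d_", ch)]] <- samples[[ch]] -
      interp(baselines[[ch]], samples$time_s)
    out[[ch]] <- NULL
  }
  out
}

#' Water-vapor dilution correction
#'
#' Converts wet gas fractions and wet flow to dry equivalents using the
#' dilution factor `d = 1 - wvp/bp`: dry fraction = wet / d, dry flow =
#' wet flow * d. Exact inverse of re-wetting.
#'
#' @param fo2,fco2 Wet fractional concentrations.
#' @param wvp_kpa Water vapor pressure (kPa).
#' @param bp_kpa Barometric pressure (kPa).
#' @param flow_ml_min Wet (total) flow (ml min^-1); optional.
#' @return List with `fo2_dry`, `fco2_dry`, `flow_dry`, `dilution`.
#' @export
water_vapor_correct <- function(fo2, fco2, wvp_kpa, bp_kpa,
                                flow_ml_min = NULL) {
  if (any(wvp_kpa < 0) || any(wvp_kpa >= bp_kpa))
    stop("need 0 <= wvp < bp", call. = FALSE)
  d <- 1 - wvp_kpa / bp_kpa
  list(fo2_dry = fo2 / d, fco2_dry = fco2 / d,
       flow_dry = if (is.null(flow_ml_min)) NULL else flow_ml_min * d,
       dilution = d)
}

#' Gas-exchange rates from baselined window deltas
#'
#' Pull-mode mass balance for a leaky, ambient-pressure chamber with both
#' gases measured and water vapor mathematically removed. Because the net
#' respiratory volume flux (VO2 - VCO2 - VH2O vapor) is far below the pull
#' flow, incurrent and excurrent dry flows are taken as equal, giving
#' `VO2 = -flow_dry * dFo2_dry`, `VCO2 = flow_dry * dFco2_dry`. Water loss
#' comes from the vapor-pressure excess carried by the total flow,
#' `VH2O(vapor ml) = flow * dwvp / bp`, converted to mg at STP
#' (22414 ml mol^-1, 18.02 g mol^-1). Reported VH2O is uncorrected for
#' fecal/spilled water.
#'
#' @param deltas data.frame from [baseline_correct()] on dried windows:
#'   columns `d_fo2_dry`, `d_fco2_dry`, `d_wvp_kpa`, `flow_dry`,
#'   `flow_ml_min`, `bp_kpa`, `chamber`, `time_s`.
#' @return data.frame of metabolic points: `time_s`, `chamber`,
#'   `vo2_ml_min`, `vco2_ml_min`, `vh2o_mg_min`.
#' @export
compute_exchange_rates <- function(deltas) {
  for (ch in c("d_fo2_dry", "d_fco2_dry", "d_wvp_kpa"))
    if (any(!is.finite(deltas[[ch]])))
      stop(sprintf("non-finite deltas in %s", ch), call. = FALSE)
  data.frame(time_s = deltas$time_s, chamber = deltas$chamber,
             vo2_ml_min = -deltas$d_fo2_dry * deltas$flow_dry,
             vco2_ml_min = deltas$d_fco2_dry * deltas$flow_dry,
             vh2o_mg_min = deltas$flow_ml_min * deltas$d_wvp_kpa /
               deltas$bp_kpa / ML_VAPOR_PER_MG_H2O)
}

#' Process a multiplexed gas trace into metabolic points
#'
#' The full macro: lag alignment, per-dwell instantaneous (z-transform)
#' correction of the O2 channel using the chamber time constant, stable
#' window extraction, per-window water-vapor drying, baseline interpolation,
#' and the pull-mode gas-exchange equations. Water-vapor drying precedes
#' baselining so that each window is corrected with its own vapor pressure
#' (baselining wet fractions would leave a dilution artifact of order
#' `FiO2 * VH2O / flow`).
#'
#' @details
#' The O2 and CO2 channels are converted to dry fractions sample-by-sample
#' (within each dwell, using a within-dwell smoothed vapor pressure for the
#' dilution factor — vapor pressure varies at the chamber time constant, so
#' the smoothing adds no bias but keeps wvp sensor noise out of the
#' z-transform's derivative) before the instantaneous correction, so the
#' correction inverts the dry-gas washout dynamics directly.
#'
#' @param trace Gas trace data.frame (see [simulate_multiplexed_trace()] or
#'   [read_gas_trace()]).
#' @param schedule [sampling_schedule()].
#' @param chamber [chamber_config()] (geometry for the time constant).
#' @param analyzer [analyzer_model()] (lags).
#' @param tau_s Optional chamber washout time constant override (seconds);
#'   default `60 * volume / flow`. Effective volume may differ from
#'   geometric volume.
#' @param smoothing_window_s Smoothing before differentiation (s).
#' @param z_transform Apply the instantaneous correction (default TRUE).
#' @param wvp_smooth_s Within-dwell smoothing of the vapor-pressure channel
#'   used for the dilution factor (s).
#' @param washout_aware_water Baseline the water channel against the ambient
#'   vapor pressure passed through the chamber's first-order dynamics (the
#'   chamber smooths ambient humidity fluctuations with time constant `tau`;
#'   subtracting raw interpolated ambient would leave a lag artifact of order
#'   `tau * d(wvp_ambient)/dt` in VH2O). Default TRUE.
#' @return data.frame of metabolic points (`time_s`, `chamber`,
#'   `vo2_ml_min`, `vco2_ml_min`, `vh2o_mg_min`).
#' @export
process_gas_trace <- function(trace, schedule, chamber,
                              analyzer = analyzer_model(), tau_s = NULL,
                              smoothing_window_s = 11, z_transform = TRUE,
                              wvp_smooth_s = 31, washout_aware_water = TRUE) {
  if (is.null(tau_s))
    tau_s <- 60 * chamber$volume_l * 1000 / chamber$flow_ml_min
  tr <- lag_align(trace, analyzer$lag_o2_s, analyzer$lag_co2_h2o_s)

  # per-dwell: dry the gas channels, then z-transform the dry O2
  r <- rle(tr$marker)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(ends)) {
    seg <- starts[i]:ends[i]
    w_s <- moving_average(tr$wvp_kpa[seg], min(wvp_smooth_s, r$lengths[i]))
    dil <- 1 - pmax(pmin(w_s, 0.2 * tr$bp_kpa[seg]), 0) / tr$bp_kpa[seg]
    tr$fo2[seg] <- tr$fo2[seg] / dil
    tr$fco2[seg] <- tr$fco2[seg] / dil
    if (z_transform && r$values[i] != 0L &&
        r$lengths[i] >= smoothing_window_s) {
      tr$fo2[seg] <- instantaneous_correct(tr$fo2[seg], tau_s,
                                           smoothing_window_s)
      # chamber washout delays CO2 identically; invert it the same way
      tr$fco2[seg] <- instantaneous_correct(tr$fco2[seg], tau_s,
                                            smoothing_window_s)
    }
  }

  win <- extract_stable_windows(tr, schedule)
  win$flow_dry <- win$flow_ml_min * (1 - win$wvp_kpa / win$bp_kpa)
  names(win)[names(win) == "fo2"] <- "fo2_dry"
  names(win)[names(win) == "fco2"] <- "fco2_dry"
  is_base <- win$chamber == 0L

  samples <- win[!is_base, , drop = FALSE]
  bases <- win[is_base, , drop = FALSE]
  deltas <- baseline_correct(samples, bases,
                             channels = c("fo2_dry", "fco2_dry", "wvp_kpa"))

  if (washout_aware_water && nrow(bases) >= 2L) {
    tt <- tr$time_s
    amb <- stats::approx(bases$time_s, bases$wvp_kpa, xout = tt, rule = 2,
                         ties = "ordered")$y
    filt <- recursive_relax(amb, exp(-1 / tau_s), amb[1])
    # segment indices: the trace is contiguous 1 Hz starting at tt[1]
    cf <- cumsum(filt)
    seg_len <- 15L                   # extract_stable_windows default
    j0 <- as.integer(samples$seg_start_s - tt[1]) + 1L
    j1 <- pmin(j0 + seg_len - 1L, length(filt))
    fmean <- (cf[j1] - ifelse(j0 > 1L, cf[j0 - 1L], 0)) / (j1 - j0 + 1L)
    deltas$d_wvp_kpa <- samples$wvp_kpa - fmean
  }
  compute_exchange_rates(deltas)
}
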