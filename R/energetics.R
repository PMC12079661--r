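# Weir (1949) protein-free coefficients: kcal per liter of O2 consumed and
# CO2 produced, converted to kJ. Labs differ in the exact constants; these
# are the classic two-term values.
WEIR_O2_KCAL_L <- 3.941
WEIR_CO2_KCAL_L <- 1.106
KCAL_TO_KJ <- 4.184

#' Weir energy expenditure
#'
#' Protein-free Weir conversion:
#' `EE (kJ) = 4.184 * (3.941 * VO2 + 1.106 * VCO2)` with gas volumes in
#' liters STP.
#'
#' @param vo2_l,vco2_l Total O2 consumed and CO2 produced (liters).
#' @return Energy expenditure (kJ).
#' @export
weir_energy <- function(vo2_l, vco2_l) {
  if (any(vo2_l < 0) || any(vco2_l < 0))
    stop("gas volumes must be >= 0", call. = FALSE)
  KCAL_TO_KJ * (WEIR_O2_KCAL_L * vo2_l + WEIR_CO2_KCAL_L * vco2_l)
}

# kJ per hour produced by 1 ml O2/min sustained for an hour, at a given RQ.
#' @keywords internal
kj_per_h_per_ml_o2_min <- function(rq) {
  0.06 * KCAL_TO_KJ * (WEIR_O2_KCAL_L + WEIR_CO2_KCAL_L * rq)
}

# Trapezoidal integral of a piecewise-linear rate over [t0, t1] (seconds),
# rate in units per minute; returns units (e.g. ml). Knots outside the data
# range contribute nothing.
#' @keywords internal
trapz_bin <- function(time_s, rate, t0, t1) {
  lo <- max(t0, time_s[1]); hi <- min(t1, time_s[length(time_s)])
  if (hi <= lo) return(NA_real_)
  inside <- time_s > lo & time_s < hi
  tt <- c(lo, time_s[inside], hi)
  vv <- stats::approx(time_s, rate, xout = tt, ties = "ordered")$y
  sum(diff(tt) * (vv[-length(vv)] + vv[-1]) / 2) / 60
}

#' Integrate gas-exchange rates into hourly or daily totals
#'
#' Area-under-the-curve (trapezoid) integration of each rate over calendar
#' bins of the experiment clock, with linear interpolation across bin
#' boundaries. Energy expenditure per bin is computed from the O2 and CO2
#' totals via [weir_energy()]. Bins whose data coverage (time spanned by
#' bracketing points / bin width) falls below `coverage_min` are flagged.
#'
#' @param points data.frame of metabolic points: `time_s`, `chamber`,
#'   `vo2_ml_min`, `vco2_ml_min`, `vh2o_mg_min` (one chamber/bird).
#' @param bin `"hour"` or `"day"`.
#' @param coverage_min Minimum covered fraction for an unflagged bin.
#' @return data.frame with `bin_start_s`, totals `o2_ml`, `co2_ml`,
#'   `h2o_mg`, `ee_kj`, mean rate `vh2o_mg_min`, `n_points`, `coverage`,
#'   `flagged`.
#' @export
integrate_rates <- function(points, bin = c("hour", "day"),
                            coverage_min = 0.5) {
  bin <- match.arg(bin)
  width <- if (bin == "hour") 3600 else 86400
  if (nrow(points) == 0L)
    return(data.frame(bin_start_s = numeric(), o2_ml = numeric(),
                      co2_ml = numeric(), h2o_mg = numeric(),
                      ee_kj = numeric(), vh2o_mg_min = numeric(),
                      n_points = integer(), coverage = numeric(),
                      flagged = logical()))
  points <- points[order(points$time_s), ]
  t <- points$time_s
  bins <- seq(floor(t[1] / width) * width, t[length(t)], by = width)
  res <- lapply(bins, function(b0) {
    b1 <- b0 + width
    lo <- max(b0, t[1]); hi <- min(b1, t[length(t)])
    cov <- max(hi - lo, 0) / width
    o2 <- trapz_bin(t, points$vo2_ml_min, b0, b1)
    co2 <- trapz_bin(t, points$vco2_ml_min, b0, b1)
    h2o <- trapz_bin(t, points$vh2o_mg_min, b0, b1)
    covered_min <- max(hi - lo, 0) / 60
    np <- sum(t >= b0 & t < b1)
    if (np == 0L) o2 <- co2 <- h2o <- NA_real_  # no data inside the bin
    data.frame(bin_start_s = b0, o2_ml = o2, co2_ml = co2, h2o_mg = h2o,
               ee_kj = if (is.na(o2)) NA_real_
                       else weir_energy(max(o2, 0) / 1000,
                                        max(co2, 0) / 1000),
               vh2o_mg_min = if (covered_min > 0 && !is.na(h2o))
                               h2o / covered_min else NA_real_,
               n_points = np,
               coverage = cov, flagged = cov < coverage_min || np == 0L)
  })
  do.call(rbind, res)
}

#' Daily minimum metabolic rate
#'
#' Mean of the two lowest VO2 measurements per 24 h calendar day of the
#' experiment clock (day boundaries at experiment midnight). Days with fewer
#' than two points are skipped with a warning.
#'
#' @param points data.frame with `time_s` and `vo2_ml_min`.
#' @return data.frame with `day`, `min_vo2_ml_min`, `n_points`.
#' @export
daily_min_mr <- function(points) {
  day <- floor(points$time_s / 86400)
  out <- lapply(sort(unique(day)), function(d) {
    v <- points$vo2_ml_min[day == d]
    if (length(v) < 2L) {
      warning(sprintf("day %d has < 2 points; skipped", d), call. = FALSE)
      return(NULL)
    }
    data.frame(day = d, min_vo2_ml_min = mean(sort(v)[1:2]),
               n_points = length(v))
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(day = numeric(), min_vo2_ml_min = numeric(),
                      n_points = integer())
  out
}
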