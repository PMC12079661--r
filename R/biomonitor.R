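# Load-cell biomonitoring pipeline: calibration, rolling statistics,
# minimum-SD point selection, error-propagated differencing, 3-SD outlier
# rejection, refill / body-mass recode classification, intake and mass
# aggregation, and drift metrics.

#' Calibrate a load cell by ordinary least squares
#'
#' Fits `grams = offset + scale * counts` to reference weights (the bench
#' calibration normally done with 25-200 g weights).
#'
#' @param counts Raw ADC counts at each reference mass.
#' @param reference_g Reference masses (g); at least two distinct values.
#' @return List: `scale` (g/count), `offset` (g), `rms` residual (g).
#' @export
calibrate_load_cell <- function(counts, reference_g) {
  if (length(unique(reference_g)) < 2L)
    stop("need >= 2 distinct reference masses", call. = FALSE)
  fit <- stats::lm(reference_g ~ counts)
  list(scale = unname(stats::coef(fit)[2]),
       offset = unname(stats::coef(fit)[1]),
       rms = sqrt(mean(stats::residuals(fit)^2)))
}

#' Select the most stable rolling mean per 10-minute block
#'
#' Computes a centered rolling mean and SD (window `roll_window_s`) of a 1 Hz
#' channel and, within each consecutive `block_s` block, keeps the rolling
#' mean with the lowest rolling SD (ties broken earliest). Blocks too short
#' to hold a full rolling window are skipped. This is the data-reduction
#' step: 1 Hz input becomes at most one point per channel per block.
#'
#' @param time_s 1 Hz timestamps (s).
#' @param value Channel values (g).
#' @param roll_window_s Rolling window (s, default 60).
#' @param block_s Selection block (s, default 600).
#' @return data.frame: `time_s` (center of the selected window), `value_g`
#'   (rolling mean), `sd_g` (rolling SD).
#' @export
stable_point_selection <- function(time_s, value, roll_window_s = 60,
                                   block_s = 600) {
  n <- length(value)
  if (n == 0L)
    return(data.frame(time_s = numeric(), value_g = numeric(),
                      sd_g = numeric()))
  rs <- roll_mean_sd(value, roll_window_s)
  ok <- which(!is.na(rs$sd))
  if (!length(ok))
    return(data.frame(time_s = numeric(), value_g = numeric(),
                      sd_g = numeric()))
  block <- floor(time_s[ok] / block_s)
  o <- order(block, rs$sd[ok], time_s[ok])
  keep <- ok[o][!duplicated(block[o])]
  keep <- sort(keep)
  data.frame(time_s = time_s[keep], value_g = rs$mean[keep],
             sd_g = rs$sd[keep])
}

#' Difference stable points with error propagation and 3-SD rejection
#'
#' Computes lag differences between consecutive stable points,
#' `delta_i = x_{i+1} - x_i`, propagating the selection SDs as
#' `sd_delta = sqrt(sd_i^2 + sd_{i+1}^2)`. Deltas farther than `outlier_sd`
#' standard deviations from the channel's mean delta are classed
#' `rejected_outlier`. Structural events larger than `exclude_threshold`
#' (refills, dish-perching steps — classified downstream) are excluded from
#' the reference mean/SD and never rejected here; set
#' `exclude_threshold = Inf` to use the plain full-record mean/SD.
#'
#' @param points data.frame from [stable_point_selection()]; an optional
#'   `segment` column limits differencing to within segments (tare splits).
#' @param outlier_sd Rejection multiple (default 3).
#' @param exclude_threshold |delta| above which a delta is treated as a
#'   structural event (default 20 g).
#' @return data.frame of events: `time_s` (midpoint), `delta_g`,
#'   `sd_delta_g`, `class` (`rejected_outlier` or NA).
#' @export
lag_difference_filter <- function(points, outlier_sd = 3,
                                  exclude_threshold = 20) {
  seg <- if ("segment" %in% names(points)) points$segment
         else rep(1L, nrow(points))
  out <- lapply(split(seq_len(nrow(points)), seg), function(i) {
    if (length(i) < 2L) return(NULL)
    p <- points[i, ]
    k <- seq_len(nrow(p) - 1L)
    data.frame(time_s = (p$time_s[k] + p$time_s[k + 1L]) / 2,
               t0_s = p$time_s[k], t1_s = p$time_s[k + 1L],
               delta_g = p$value_g[k + 1L] - p$value_g[k],
               sd_delta_g = sqrt(p$sd_g[k]^2 + p$sd_g[k + 1L]^2))
  })
  ev <- do.call(rbind, out)
  if (is.null(ev))
    return(data.frame(time_s = numeric(), t0_s = numeric(),
                      t1_s = numeric(), delta_g = numeric(),
                      sd_delta_g = numeric(), class = character()))
  ev <- ev[order(ev$time_s), ]
  rownames(ev) <- NULL
  ref <- abs(ev$delta_g) <= exclude_threshold
  ev$class <- NA_character_
  if (sum(ref) >= 2L) {
    m <- mean(ev$delta_g[ref]); s <- stats::sd(ev$delta_g[ref])
    if (s > 0)
      ev$class[ref & abs(ev$delta_g - m) > outlier_sd * s] <-
        "rejected_outlier"
  }
  ev
}

#' Classify mass deltas into consumption, refill and body-mass recodes
#'
#' On food/water channels: |delta| in (refill_g, recode_max_g] is recoded as
#' a body-mass measurement (birds sleeping on the dish), |delta| above
#' `recode_max_g` is a refill / perching exclusion, and the remaining
#' sub-threshold deltas are consumption (negative) or spillage/drift
#' (positive). The perch channel passes through unrecoded.
#'
#' @param events data.frame from [lag_difference_filter()].
#' @param channel `"food"`, `"water"` or `"perch"`.
#' @param refill_g Structural-event threshold (g, default 20).
#' @param recode_max_g Upper bound of the body-mass recode band (g).
#' @return `events` with filled `class` and, for recodes, `mass_g = |delta|`
#'   and `direction` (step-on `+` / step-off `-`).
#' @export
classify_mass_events <- function(events, channel, refill_g = 20,
                                 recode_max_g = 35) {
  events$mass_g <- NA_real_
  events$direction <- NA_character_
  if (nrow(events) == 0L) return(events)
  if (channel == "perch") {
    events$class[is.na(events$class)] <- "perch_step"
    return(events)
  }
  a <- abs(events$delta_g)
  recode <- a > refill_g & a <= recode_max_g
  refill <- a > recode_max_g
  events$class[recode] <- "body_mass_recode"
  events$mass_g[recode] <- a[recode]
  events$direction[recode] <- ifelse(events$delta_g[recode] > 0, "+", "-")
  events$class[refill] <- "refill"
  events$class[is.na(events$class)] <- "consumption"
  events
}

#' Aggregate intake and body mass per hour or day
#'
#' Food and water per bin are the negated sums of the (negative) consumption
#' deltas. Each delta spans the gap between two stable points (roughly ten
#' minutes), so its mass is attributed to bins in proportion to the gap's
#' overlap with each bin (events without gap endpoints fall back to midpoint
#' assignment). Body mass per bin is the mean of perch stable points within
#' the plausibility band plus recoded body-mass events. Empty bins report
#' zero intake but missing (NA) mass.
#'
#' @param food_events,water_events Classified event tables.
#' @param perch_points Perch [stable_point_selection()] output.
#' @param bin `"hour"` or `"day"`.
#' @param mass_band_g Plausible body-mass band for perch points (g).
#' @param span_s Optional `c(start, end)` of the record (s, end exclusive);
#'   default from the data.
#' @return data.frame: `bin_start_s`, `food_g`, `water_g`, `mass_g`,
#'   `n_mass`.
#' @export
aggregate_intake <- function(food_events, water_events, perch_points,
                             bin = c("hour", "day"),
                             mass_band_g = c(15, 45), span_s = NULL) {
  bin <- match.arg(bin)
  width <- if (bin == "hour") 3600 else 86400
  all_t <- c(food_events$time_s, water_events$time_s, perch_points$time_s)
  if (is.null(span_s)) {
    if (!length(all_t))
      return(data.frame(bin_start_s = numeric(), food_g = numeric(),
                        water_g = numeric(), mass_g = numeric(),
                        n_mass = integer()))
    span_s <- range(all_t)
  }
  hi <- if (span_s[2] %% width == 0) span_s[2] - 1 else span_s[2]
  bins <- seq(floor(span_s[1] / width) * width, max(hi, span_s[1]),
              by = width)

  sum_cons <- function(ev, b0) {
    sel <- ev$class == "consumption" & ev$delta_g < 0
    if (!any(sel)) return(0)
    e <- ev[sel, ]
    if (all(c("t0_s", "t1_s") %in% names(e)) && all(e$t1_s > e$t0_s)) {
      w <- (pmin(e$t1_s, b0 + width) - pmax(e$t0_s, b0)) / (e$t1_s - e$t0_s)
      -sum(e$delta_g * pmax(w, 0))
    } else {
      inb <- e$time_s >= b0 & e$time_s < b0 + width
      -sum(e$delta_g[inb])
    }
  }
  mass_pts <- function(b0) {
    pp <- perch_points$value_g[perch_points$time_s >= b0 &
                                 perch_points$time_s < b0 + width]
    pp <- pp[pp >= mass_band_g[1] & pp <= mass_band_g[2]]
    rec <- c(food_events$mass_g[food_events$class == "body_mass_recode" &
                                  food_events$time_s >= b0 &
                                  food_events$time_s < b0 + width],
             water_events$mass_g[water_events$class == "body_mass_recode" &
                                   water_events$time_s >= b0 &
                                   water_events$time_s < b0 + width])
    c(pp, rec[!is.na(rec)])
  }
  res <- lapply(bins, function(b0) {
    m <- mass_pts(b0)
    data.frame(bin_start_s = b0,
               food_g = sum_cons(food_events, b0),
               water_g = sum_cons(water_events, b0),
               mass_g = if (length(m)) mean(m) else NA_real_,
               n_mass = length(m))
  })
  do.call(rbind, res)
}

#' Daily sensor drift (max minus min)
#'
#' Per calendar day of the experiment clock, the range of the channel's
#' stable points — the empty-chamber drift diagnostic.
#'
#' @param points [stable_point_selection()] output for one channel.
#' @return data.frame: `day`, `drift_g`, `n_points`.
#' @export
sensor_drift <- function(points) {
  day <- floor(points$time_s / 86400)
  out <- lapply(sort(unique(day)), function(d) {
    v <- points$value_g[day == d]
    if (length(v) < 2L) return(NULL)
    data.frame(day = d, drift_g = max(v) - min(v), n_points = length(v))
  })
  do.call(rbind, out)
}

#' Run the full load-cell pipeline on one mass trace
#'
#' Per channel: split the record at tare events, select minimum-SD stable
#' points, difference with error propagation and 3-SD rejection, classify
#' refill / body-mass-recode / consumption events, and aggregate hourly and
#' daily intake and body mass.
#'
#' The 3-SD rule flags *measurements taken during unstable periods*. With
#' `rejected = "merge"` (default), the less stable endpoint of each flagged
#' difference is removed and the record re-differenced once, so the flagged
#' point's mass is carried by a single spanning delta and consumption is
#' conserved; `rejected = "drop"` discards flagged deltas outright (and the
#' consumption they carry).
#'
#' @param trace 1 Hz mass trace (`time_s`, `perch_g`, `food_g`, `water_g`),
#'   e.g. from [simulate_load_cells()] or [read_arduino_log()].
#' @param thresholds Threshold list (see [experiment_config()]).
#' @param tare_times Tare timestamps (s); defaults to the trace attribute.
#' @param rejected How flagged deltas are handled: `"merge"` or `"drop"`.
#' @return List: `points` (per channel, after any merge removals), `events`
#'   (per channel), `hourly`, `daily`.
#' @export
process_mass_trace <- function(trace,
                               thresholds = experiment_config()$thresholds,
                               tare_times = attr(trace, "tare_times"),
                               rejected = c("merge", "drop")) {
  th <- thresholds
  rejected <- match.arg(rejected)
  if (is.null(tare_times)) tare_times <- 0
  seg_of <- function(t) findInterval(t, sort(unique(c(0, tare_times))))

  run_channel <- function(col) {
    pts <- stable_point_selection(trace$time_s, trace[[col]],
                                  th$roll_window_s, th$block_s)
    pts$segment <- seg_of(pts$time_s)
    pts
  }
  points <- list(perch = run_channel("perch_g"),
                 food = run_channel("food_g"),
                 water = run_channel("water_g"))
  events <- list()
  for (ch in names(points)) {
    ev <- lag_difference_filter(points[[ch]], th$outlier_sd, th$refill_g)
    rej <- which(ev$class == "rejected_outlier")
    if (rejected == "merge" && length(rej)) {
      # remove the less stable endpoint of every flagged difference and
      # re-difference once (no second rejection pass)
      drop <- unique(vapply(rej, function(i) {
        k0 <- match(ev$t0_s[i], points[[ch]]$time_s)
        k1 <- match(ev$t1_s[i], points[[ch]]$time_s)
        if (points[[ch]]$sd_g[k0] > points[[ch]]$sd_g[k1]) k0 else k1
      }, integer(1)))
      points[[ch]] <- points[[ch]][-drop, ]
      ev <- lag_difference_filter(points[[ch]], Inf, th$refill_g)
    }
    events[[ch]] <- classify_mass_events(ev, ch, th$refill_g,
                                         th$recode_max_g)
  }

  span <- range(trace$time_s)
  hourly <- aggregate_intake(events$food, events$water, points$perch,
                             "hour", th$mass_band_g, span)
  daily <- aggregate_intake(events$food, events$water, points$perch,
                            "day", th$mass_band_g, span)
  list(points = points, events = events, hourly = hourly, daily = daily)
}
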