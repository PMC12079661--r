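#' Chamber and flow configuration
#'
#' Geometry and plumbing of one live-in respirometry chamber and the shared
#' multiplexed analyzer chain. Defaults follow a 13 liter chamber pulled at
#' 1700 ml min^-1 with 60 s dwells on seven chambers plus a 60 s ambient
#' baseline, subsampled at 700 ml min^-1.
#'
#' @param volume_l Chamber volume (liters).
#' @param flow_ml_min Pull flow per chamber (ml min^-1, STP).
#' @param n_chambers Number of chambers on the multiplexer.
#' @param dwell_s Seconds the analyzers sample each chamber per cycle.
#' @param baseline_dwell_s Seconds on ambient baseline per cycle.
#' @param subsample_ml_min Subsampler flow to the analyzers (ml min^-1).
#' @param bp_kpa Barometric pressure (kPa).
#' @return A `chamber_config` list.
#' @export
chamber_config <- function(volume_l = 13, flow_ml_min = 1700, n_chambers = 7,
                           dwell_s = 60, baseline_dwell_s = 60,
                           subsample_ml_min = 700, bp_kpa = 101.3) {
  assert_scalar_pos(volume_l, "volume_l")
  assert_scalar_pos(flow_ml_min, "flow_ml_min")
  assert_scalar_pos(dwell_s, "dwell_s")
  assert_scalar_pos(baseline_dwell_s, "baseline_dwell_s")
  assert_scalar_pos(bp_kpa, "bp_kpa")
  structure(list(volume_l = volume_l, flow_ml_min = flow_ml_min,
                 n_chambers = as.integer(n_chambers), dwell_s = dwell_s,
                 baseline_dwell_s = baseline_dwell_s,
                 subsample_ml_min = subsample_ml_min, bp_kpa = bp_kpa),
            class = "chamber_config")
}

#' Physiological parameters of a simulated bird
#'
#' Scholander-type piecewise-linear metabolic model: below the lower critical
#' temperature VO2 rises linearly with thermal conductance; above it VO2 is
#' flat at `bmr`. A circadian activity factor multiplies the whole rate
#' (`activity_multiplier` during lights-on, `2 - activity_multiplier` during
#' lights-off, so the 24 h mean is 1). Evaporative water loss scales
#' multiplicatively with air temperature and relative humidity. Feeding and
#' drinking are coupled to the bird's realized hourly energy expenditure:
#' food (g/h) = `feed_rate + food_ee_slope * (EE_h - ee_ref_kj)` and
#' water (g/h) = `drink_rate * (1 + water_ee_pct/100)^(EE_h - ee_ref_kj)`,
#' lights-on hours only.
#'
#' @param body_mass_g Body mass (g).
#' @param bmr_ml_min Thermoneutral 24 h-mean oxygen consumption (ml O2 min^-1).
#' @param lct_c Lower critical temperature (deg C).
#' @param conductance Extra VO2 per degree below `lct_c`
#'   (ml O2 min^-1 degC^-1). Default reproduces an hourly energy-expenditure
#'   slope of 0.05 kJ per degree via [conductance_for_ee_slope()].
#' @param rq Respiratory quotient VCO2/VO2.
#' @param ewl_base_mg_min Evaporative water loss at 25 deg C and 40% RH
#'   (mg min^-1).
#' @param ewl_temp_coeff Fractional EWL change per deg C (default +5%).
#' @param ewl_rh_coeff Fractional EWL change per %RH (default -4%).
#' @param activity_multiplier Lights-on activity factor (lights-off uses
#'   `2 - activity_multiplier`).
#' @param feed_rate_g_h Food intake per lights-on hour at the reference EE.
#' @param drink_rate_g_h Water intake per lights-on hour at the reference EE.
#' @param food_ee_slope Extra food (g) per kJ of hourly EE above `ee_ref_kj`.
#' @param water_ee_pct Percent change in hourly water per kJ of hourly EE.
#' @param ee_ref_kj Reference hourly EE (kJ) anchoring the intake couplings.
#' @param pn_vo2_sd,pn_ewl_sd SDs of the hour-level lognormal physiological
#'   noise on VO2 and EWL (biological variability; set 0 for deterministic
#'   truth).
#' @param intake_noise_sd SD of the additive hour-level noise on the intake
#'   targets (g for food; lognormal SD for water).
#' @param tb_day_c,tb_night_c Core body temperature by photophase (deg C).
#' @param p_sleep_on_dish Probability a given night is slept on the food dish
#'   (generates the 20-35 g recode events).
#' @return A `bird_params` list.
#' @export
bird_params <- function(body_mass_g = 27, bmr_ml_min = 1.5, lct_c = 25,
                        conductance = conductance_for_ee_slope(0.05, rq),
                        rq = 0.85,
                        ewl_base_mg_min = 1.5, ewl_temp_coeff = 0.05,
                        ewl_rh_coeff = -0.04, activity_multiplier = 1.15,
                        feed_rate_g_h = 5.7 / 12, drink_rate_g_h = 9.4 / 12,
                        food_ee_slope = 0.1, water_ee_pct = 17,
                        ee_ref_kj = 2.11,
                        pn_vo2_sd = 0.02, pn_ewl_sd = 0.05,
                        intake_noise_sd = 0.05,
                        tb_day_c = 41.5, tb_night_c = 40.5,
                        p_sleep_on_dish = 0.3) {
  for (nm in c("body_mass_g", "bmr_ml_min", "rq"))
    assert_scalar_pos(get(nm), nm)
  assert_scalar_pos(conductance, "conductance", strict = FALSE)
  assert_finite(lct_c, "lct_c")
  assert_scalar_pos(ewl_base_mg_min, "ewl_base_mg_min")
  assert_finite(ewl_temp_coeff, "ewl_temp_coeff")
  assert_finite(ewl_rh_coeff, "ewl_rh_coeff")
  assert_scalar_pos(activity_multiplier, "activity_multiplier")
  if (rq > 1.05) stop("'rq' must be <= 1.05", call. = FALSE)
  structure(list(body_mass_g = body_mass_g, bmr_ml_min = bmr_ml_min,
                 lct_c = lct_c, conductance = conductance, rq = rq,
                 ewl_base_mg_min = ewl_base_mg_min,
                 ewl_temp_coeff = ewl_temp_coeff,
                 ewl_rh_coeff = ewl_rh_coeff,
                 activity_multiplier = activity_multiplier,
                 feed_rate_g_h = feed_rate_g_h,
                 drink_rate_g_h = drink_rate_g_h,
                 food_ee_slope = food_ee_slope, water_ee_pct = water_ee_pct,
                 ee_ref_kj = ee_ref_kj,
                 pn_vo2_sd = pn_vo2_sd, pn_ewl_sd = pn_ewl_sd,
                 intake_noise_sd = intake_noise_sd,
                 tb_day_c = tb_day_c, tb_night_c = tb_night_c,
                 p_sleep_on_dish = p_sleep_on_dish),
            class = "bird_params")
}

#' Thermal conductance that yields a target hourly EE slope
#'
#' Converts a target energy-expenditure slope (kJ per hour per deg C below the
#' lower critical temperature) into the equivalent thermal conductance in
#' ml O2 min^-1 degC^-1, using the Weir conversion at respiratory quotient
#' `rq` and a mean activity factor of `activity`.
#'
#' @param slope_kj_per_degc Target |dEE/dT| (kJ h^-1 degC^-1).
#' @param rq Respiratory quotient.
#' @param activity Mean activity factor (default 1).
#' @return Conductance (ml O2 min^-1 degC^-1).
#' @export
conductance_for_ee_slope <- function(slope_kj_per_degc, rq = 0.85,
                                     activity = 1) {
  slope_kj_per_degc / (kj_per_h_per_ml_o2_min(rq) * activity)
}

#' Gas analyzer chain model
#'
#' Transport lags, first-order analyzer response, additive Gaussian noise and
#' slow linear span drift for the multiplexed analyzer chain. The default
#' response time constant of 3 s gives a 10-90% step time of
#' `log(9) * 3 = 6.6 s`.
#'
#' @param lag_o2_s,lag_co2_h2o_s Transport lags (s).
#' @param response_tau_s First-order analyzer response time constant (s).
#' @param noise_sd Named numeric: 1 Hz noise SD for `fo2`, `fco2` (fraction
#'   units) and `wvp` (kPa).
#' @param drift_per_h Named numeric: linear span drift per hour, same units.
#' @return An `analyzer_model` list.
#' @export
analyzer_model <- function(lag_o2_s = 7, lag_co2_h2o_s = 5,
                           response_tau_s = 3,
                           noise_sd = c(fo2 = 1e-6, fco2 = 5e-7, wvp = 2e-3),
                           drift_per_h = c(fo2 = 2e-5, fco2 = 2e-6,
                                           wvp = 1e-3)) {
  assert_scalar_pos(lag_o2_s, "lag_o2_s", strict = FALSE)
  assert_scalar_pos(lag_co2_h2o_s, "lag_co2_h2o_s", strict = FALSE)
  assert_scalar_pos(response_tau_s, "response_tau_s", strict = FALSE)
  structure(list(lag_o2_s = lag_o2_s, lag_co2_h2o_s = lag_co2_h2o_s,
                 response_tau_s = response_tau_s,
                 noise_sd = noise_sd, drift_per_h = drift_per_h),
            class = "analyzer_model")
}

#' Load-cell sensor model
#'
#' 1 Hz Gaussian noise plus linear per-channel drift, reset at tare events.
#' Default daily drifts are 0.5 g (perch), 0.04 g (food) and 0.05 g (water).
#'
#' @param noise_sd_g 1 Hz noise SD (g).
#' @param drift_perch_g_day,drift_food_g_day,drift_water_g_day Linear drift
#'   (g per day).
#' @param tare_interval_days Days between tare resets (drift re-zeroed).
#' @return A `load_cell_model` list.
#' @export
load_cell_model <- function(noise_sd_g = 0.05, drift_perch_g_day = 0.5,
                            drift_food_g_day = 0.04,
                            drift_water_g_day = 0.05,
                            tare_interval_days = 2) {
  for (nm in c("noise_sd_g", "drift_perch_g_day", "drift_food_g_day",
               "drift_water_g_day"))
    assert_scalar_pos(get(nm), nm, strict = FALSE)
  assert_scalar_pos(tare_interval_days, "tare_interval_days")
  structure(list(noise_sd_g = noise_sd_g,
                 drift_perch_g_day = drift_perch_g_day,
                 drift_food_g_day = drift_food_g_day,
                 drift_water_g_day = drift_water_g_day,
                 tare_interval_days = tare_interval_days),
            class = "load_cell_model")
}

#' Multiplexer sampling schedule
#'
#' One cycle visits the listed chambers in order, each for `dwell_s`, with an
#' ambient baseline slot (chamber id 0) of `baseline_dwell_s` at the start of
#' each cycle. Cycle period is `baseline_dwell_s + length(chambers)*dwell_s`;
#' with 7 chambers and 60 s dwells each animal is measured every 480 s.
#'
#' @param chambers Integer chamber ids in sampling order.
#' @param dwell_s Dwell per chamber (s).
#' @param baseline_dwell_s Baseline dwell (s).
#' @return A `sampling_schedule` with `slots` (data.frame of `chamber`,
#'   `dwell_s`) and `cycle_period_s`.
#' @export
sampling_schedule <- function(chambers = 1:7, dwell_s = 60,
                              baseline_dwell_s = 60) {
  assert_scalar_pos(dwell_s, "dwell_s")
  assert_scalar_pos(baseline_dwell_s, "baseline_dwell_s")
  chambers <- as.integer(chambers)
  if (anyDuplicated(chambers) || any(chambers < 1))
    stop("'chambers' must be distinct positive ids", call. = FALSE)
  slots <- data.frame(chamber = c(0L, chambers),
                      dwell_s = c(baseline_dwell_s,
                                  rep(dwell_s, length(chambers))))
  structure(list(slots = slots, cycle_period_s = sum(slots$dwell_s)),
            class = "sampling_schedule")
}

#' Staircase temperature program
#'
#' Ambient temperature held constant within each day and stepped down daily
#' from `from` to `to` over `days` days (the acute cold-acclimation design:
#' 25 to 5 deg C over 10 days). Each step is a linear transition over
#' `transition_s` seconds starting at midnight — an environmental chamber
#' cannot change temperature instantaneously, and a discontinuous step would
#' put spurious washout transients into every downstream oracle.
#'
#' @param days Number of days.
#' @param from,to Start and end temperatures (deg C).
#' @param transition_s Ramp duration of each daily step (s).
#' @return data.frame with `time_s`, `temp_c` breakpoints; interpolate with
#'   [program_value()] using `method = "linear"`.
#' @export
temperature_program <- function(days = 10, from = 25, to = 5,
                                transition_s = 1800) {
  nd <- max(1L, as.integer(round(days)))
  temps <- seq(from, to, length.out = nd)
  if (nd == 1L) return(data.frame(time_s = 0, temp_c = temps[1]))
  d <- seq_len(nd - 1L)
  data.frame(
    time_s = c(0, as.vector(rbind(d * 86400, d * 86400 + transition_s))),
    temp_c = c(temps[1], as.vector(rbind(temps[-nd], temps[-1]))))
}

#' Evaluate a piecewise program at arbitrary times
#'
#' @param program data.frame whose first column is `time_s` and second the
#'   value.
#' @param time_s Times to evaluate (s).
#' @param method `"linear"` (ramp between breakpoints) or `"constant"`
#'   (step program).
#' @return Numeric vector of values.
#' @export
program_value <- function(program, time_s, method = c("linear", "constant")) {
  method <- match.arg(method)
  if (nrow(program) == 1L) return(rep(program[[2]][1], length(time_s)))
  stats::approx(program[[1]], program[[2]], xout = time_s, method = method,
                rule = 2, f = 0, ties = "ordered")$y
}

#' Relative-humidity program
#'
#' Daily sinusoid around `mean_rh` with seeded day-to-day offsets, so hourly
#' RH is not a pure function of hour-of-day (required for the RH effect to be
#' identifiable next to an hour factor).
#'
#' @param days Number of days.
#' @param mean_rh Mean RH (%).
#' @param amplitude Within-day sinusoid amplitude (%).
#' @param day_sd SD of daily offsets (%).
#' @param seed RNG seed.
#' @return data.frame with `time_s` (hourly breakpoints) and `rh`.
#' @export
humidity_program <- function(days = 10, mean_rh = 40, amplitude = 8,
                             day_sd = 6, seed = 1) {
  set.seed(derive_seed(seed, 11L))
  nd <- max(1L, ceiling(days))
  t_h <- seq(0, ceiling(days * 24))    # hourly breakpoints
  offs <- stats::rnorm(nd, 0, day_sd)[pmin(t_h %/% 24, nd - 1L) + 1L]
  rh <- mean_rh + amplitude * sin(2 * pi * t_h / 24) + offs
  data.frame(time_s = t_h * 3600, rh = pmin(pmax(rh, 10), 90))
}

#' Lights schedule helper
#'
#' @param time_s Experiment-clock seconds.
#' @param lights_on_hour,lights_off_hour Clock hours bounding the photophase
#'   (default 12:12, on at 07:00).
#' @return Logical, TRUE during lights-on.
#' @export
lights_on <- function(time_s, lights_on_hour = 7, lights_off_hour = 19) {
  hod <- (time_s %% 86400) / 3600
  hod >= lights_on_hour & hod < lights_off_hour
}

#' Full experiment configuration
#'
#' Bundles chamber geometry, schedule, analyzer and load-cell models, bird
#' parameter sets, environmental programs and the processing thresholds used
#' throughout the pipeline (refill > 20 g, body-mass recode 20-35 g, 3-SD
#' outlier rule, 60 s/600 s rolling windows, 7 s/5 s lags, stable segment =
#' 50% of the final 30 s).
#'
#' @param birds List of [bird_params()] (one chamber per bird, in schedule
#'   order). Defaults to three birds spanning bmr 1.3-1.6 ml O2 min^-1.
#' @param chamber [chamber_config()].
#' @param schedule [sampling_schedule()]; defaults to the birds' chambers
#'   plus baseline.
#' @param analyzer [analyzer_model()].
#' @param load_cell [load_cell_model()].
#' @param days Experiment length (days).
#' @param temperature [temperature_program()] data.frame.
#' @param humidity [humidity_program()] data.frame (built from `seed` if
#'   missing).
#' @param lights_on_hour,lights_off_hour Photophase bounds (clock hours).
#' @param ambient List with dry incurrent fractions `fio2`, `fico2`.
#' @param refill_every_days,refill_food_g,refill_water_g Refill schedule.
#' @param thresholds List of processing thresholds (see Details in the
#'   package vignette).
#' @param seed Master seed for all stochastic components.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(birds = NULL, chamber = chamber_config(),
                              schedule = NULL, analyzer = analyzer_model(),
                              load_cell = load_cell_model(), days = 10,
                              temperature = temperature_program(days),
                              humidity = NULL,
                              lights_on_hour = 7, lights_off_hour = 19,
                              ambient = list(fio2 = 0.2095, fico2 = 4e-4),
                              refill_every_days = 4, refill_food_g = 50,
                              refill_water_g = 150,
                              thresholds = list(refill_g = 20,
                                                recode_max_g = 35,
                                                outlier_sd = 3,
                                                roll_window_s = 60,
                                                block_s = 600,
                                                stable_final_s = 30,
                                                stable_frac = 0.5,
                                                mass_band_g = c(15, 45),
                                                coverage_min = 0.5),
                              seed = 1) {
  if (is.null(birds))
    birds <- list(bird_params(bmr_ml_min = 1.35, body_mass_g = 25.5,
                              ewl_base_mg_min = 1.3),
                  bird_params(bmr_ml_min = 1.50, body_mass_g = 27.0,
                              ewl_base_mg_min = 1.5),
                  bird_params(bmr_ml_min = 1.65, body_mass_g = 28.5,
                              ewl_base_mg_min = 1.7))
  if (is.null(schedule))
    schedule <- sampling_schedule(chambers = seq_along(birds),
                                  dwell_s = chamber$dwell_s,
                                  baseline_dwell_s = chamber$baseline_dwell_s)
  if (is.null(humidity)) humidity <- humidity_program(days, seed = seed)
  structure(list(birds = birds, chamber = chamber, schedule = schedule,
                 analyzer = analyzer, load_cell = load_cell, days = days,
                 temperature = temperature, humidity = humidity,
                 lights_on_hour = lights_on_hour,
                 lights_off_hour = lights_off_hour, ambient = ambient,
                 refill_every_days = refill_every_days,
                 refill_food_g = refill_food_g,
                 refill_water_g = refill_water_g,
                 thresholds = thresholds, seed = seed),
            class = "experiment_config")
}
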