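# Bird-in-chamber simulator: generates ground-truthed 1 Hz gas, mass and
# RFID streams so the whole processing pipeline can be validated end to end.

#' Simulate true metabolic rates and behavior of one bird
#'
#' Scholander-type piecewise-linear thermoregulation below the lower critical
#' temperature, circadian activity scaling, multiplicative evaporative water
#' loss in temperature and relative humidity, and feeding/drinking bouts
#' (lights-on only) coupled to the bird's realized hourly energy expenditure.
#' Hour-level lognormal physiological noise (defaults: 2% on VO2, 5% on EWL
#' and intake) represents biological variability; the couplings act on the
#' realized noisy rates. Deterministic for a fixed seed.
#'
#' @param params [bird_params()].
#' @param days Simulated span (days; 1 Hz clock starting at experiment
#'   midnight).
#' @param temperature Temperature program data.frame (`time_s`, `temp_c`).
#' @param humidity Humidity program data.frame (`time_s`, `rh`).
#' @param lights_on_hour,lights_off_hour Photophase bounds (clock hours).
#' @param temp_method Interpolation for the temperature program
#'   (`"linear"`, the default, suits the ramped staircase of
#'   [temperature_program()]; `"constant"` gives a pure step program).
#' @param seed RNG seed.
#' @return data.frame (1 Hz) with `time_s`, `temp_c`, `rh`, `true_vo2`
#'   (ml min^-1), `true_vco2` (ml min^-1), `true_vh2o` (mg min^-1),
#'   `behavior` (perch/feed/drink/on_food_dish/off_sensors), `body_temp_c`,
#'   `cum_food_g`, `cum_water_g`. Attributes: `hourly` (truth table of hourly
#'   EE and intake targets) and `bouts`.
#' @export
simulate_bird_rates <- function(params, days = 10,
                                temperature = temperature_program(days),
                                humidity = humidity_program(days),
                                lights_on_hour = 7, lights_off_hour = 19,
                                temp_method = "linear", seed = 1) {
  stopifnot(inherits(params, "bird_params"))
  n <- as.integer(days * 86400)
  t <- seq_len(n) - 1
  set.seed(derive_seed(seed, 1L))

  ta <- program_value(temperature, t, temp_method)
  rh <- program_value(humidity, t, "linear")
  day <- lights_on(t, lights_on_hour, lights_off_hour)
  act <- ifelse(day, params$activity_multiplier,
                2 - params$activity_multiplier)
  hour <- as.integer(t %/% 3600)
  nh <- as.integer(ceiling(days * 24))

  pn_vo2 <- exp(stats::rnorm(nh, 0, params$pn_vo2_sd))
  pn_ewl <- exp(stats::rnorm(nh, 0, params$pn_ewl_sd))

  vo2 <- act * pmax(params$bmr_ml_min,
                    params$bmr_ml_min +
                      params$conductance * (params$lct_c - ta)) *
    pn_vo2[hour + 1L]
  vco2 <- params$rq * vo2
  vh2o <- params$ewl_base_mg_min *
    (1 + params$ewl_temp_coeff)^(ta - 25) *
    (1 + params$ewl_rh_coeff)^(rh - 40) * pn_ewl[hour + 1L]

  # realized hourly EE (truth), driving the intake couplings
  o2_h <- as.numeric(rowsum(vo2, hour)) / 60      # ml O2 per hour
  co2_h <- as.numeric(rowsum(vco2, hour)) / 60
  ee_h <- weir_energy(o2_h / 1000, co2_h / 1000)
  hod <- (seq_len(nh) - 1L) %% 24L
  lit <- hod >= lights_on_hour & hod < lights_off_hour

  food_h <- ifelse(lit, pmax(0, params$feed_rate_g_h +
                                  params$food_ee_slope *
                                    (ee_h - params$ee_ref_kj) +
                                  stats::rnorm(nh, 0, params$intake_noise_sd)), 0)
  water_h <- ifelse(lit, params$drink_rate_g_h *
                           (1 + params$water_ee_pct / 100)^
                             (ee_h - params$ee_ref_kj) *
                           exp(stats::rnorm(nh, 0, params$intake_noise_sd)), 0)

  # feeding/drinking bouts: sparrows feed and drink in many short bouts
  # (intake records resolve roughly one intake event per ten-minute stable
  # point), so each lights-on hour holds 12 five-minute slots carrying 10
  # feeding and 8 drinking bouts of 60 s; channels draw slots independently
  # and may overlap
  bouts <- list()
  for (h in which(lit)) {
    fslots <- sample.int(12L, 10L)      # feeding: near-continuous nibbling
    wslots <- sample.int(12L, 10L)      # drinking: frequent small draughts
    start_f <- (h - 1L) * 3600 + (fslots - 1L) * 300
    start_w <- (h - 1L) * 3600 + (wslots - 1L) * 300
    bouts[[length(bouts) + 1L]] <- data.frame(
      start_s = c(start_f, start_w),
      dur_s = 60,
      mass_g = c(rep(food_h[h] / 10, 10), rep(water_h[h] / 10, 10)),
      channel = c(rep("food", 10), rep("water", 10)))
  }
  bouts <- if (length(bouts)) do.call(rbind, bouts) else
    data.frame(start_s = numeric(), dur_s = numeric(), mass_g = numeric(),
               channel = character())

  behavior <- rep("perch", n)
  inc_food <- numeric(n)
  inc_water <- numeric(n)
  if (nrow(bouts)) {
    for (i in seq_len(nrow(bouts))) {
      idx <- seq(bouts$start_s[i] + 1L, length.out = bouts$dur_s[i])
      idx <- idx[idx <= n]
      if (bouts$channel[i] == "food") {
        behavior[idx] <- "feed"
        inc_food[idx] <- inc_food[idx] + bouts$mass_g[i] / bouts$dur_s[i]
      } else {
        behavior[idx] <- "drink"
        inc_water[idx] <- inc_water[idx] + bouts$mass_g[i] / bouts$dur_s[i]
      }
    }
  }

  # some nights are slept on the food dish (rescued later as 20-35 g
  # body-mass recodes); night k runs from dusk of day k to the next dawn
  n_nights <- as.integer(ceiling(days)) + 1L
  on_dish <- stats::runif(n_nights) < params$p_sleep_on_dish
  night_id <- floor((t - lights_off_hour * 3600) / 86400)  # -1 = pre-dusk
  is_night <- !day
  sel <- is_night & on_dish[night_id + 2L]
  behavior[sel] <- "on_food_dish"

  body_temp <- ifelse(day, params$tb_day_c, params$tb_night_c)

  out <- data.frame(time_s = t, temp_c = ta, rh = rh, true_vo2 = vo2,
                    true_vco2 = vco2, true_vh2o = vh2o, behavior = behavior,
                    body_temp_c = body_temp,
                    cum_food_g = cumsum(inc_food),
                    cum_water_g = cumsum(inc_water))
  attr(out, "hourly") <- data.frame(hour = seq_len(nh) - 1L, ee_kj = ee_h,
                                    food_g = food_h, water_g = water_h,
                                    lights = lit)
  attr(out, "bouts") <- bouts
  out
}

#' Simulate first-order chamber washout
#'
#' Perfectly mixed chamber dynamics for each gas, updated analytically per
#' 1 s step (exact exponential relaxation toward the instantaneous steady
#' state, no Euler error). O2 and CO2 are propagated on a dry-gas basis with
#' time constant `tau = volume / dry flow`; at steady state the dry outlet
#' deficit equals `VO2 / dry flow` exactly. Water vapor has its own washout
#' channel fed by the bird's evaporative water loss; reported fractions are
#' re-wetted (`wet = dry * (1 - fh2o)`) and water is reported as vapor
#' pressure.
#'
#' @param truth Output of [simulate_bird_rates()] (1 Hz).
#' @param chamber [chamber_config()].
#' @param ambient List with dry incurrent fractions `fio2`, `fico2`.
#' @param env Optional 1 Hz data.frame (`temp_c`, `rh`) giving ambient water
#'   vapor; `NULL` means dry incurrent air.
#' @return data.frame (1 Hz): `time_s`, `fo2`, `fco2` (wet fractions),
#'   `wvp_kpa`.
#' @export
simulate_chamber_washout <- function(truth, chamber,
                                     ambient = list(fio2 = 0.2095,
                                                    fico2 = 4e-4),
                                     env = NULL) {
  stopifnot(inherits(chamber, "chamber_config"))
  if (chamber$flow_ml_min <= 0)
    stop("flow must be > 0: washout undefined", call. = FALSE)
  n <- nrow(truth)
  bp <- chamber$bp_kpa
  vol_ml <- chamber$volume_l * 1000
  flow <- chamber$flow_ml_min

  fh_a <- if (is.null(env)) rep(0, n) else
    pmin(env$rh / 100 * svp_kpa(env$temp_c) / bp, 0.1)
  vh2o_ml <- truth$true_vh2o * ML_VAPOR_PER_MG_H2O

  a_h <- exp(-flow / (60 * vol_ml))
  fh_ss <- fh_a + vh2o_ml / flow
  fh <- recursive_relax(fh_ss, a_h, fh_ss[1])

  fr_dry <- flow * (1 - fh)
  a_d <- exp(-mean(fr_dry) / (60 * vol_ml))
  fo2_ss <- ambient$fio2 - truth$true_vo2 / fr_dry
  fco2_ss <- ambient$fico2 + truth$true_vco2 / fr_dry
  fo2_dry <- recursive_relax(fo2_ss, a_d, fo2_ss[1])
  fco2_dry <- recursive_relax(fco2_ss, a_d, fco2_ss[1])

  data.frame(time_s = truth$time_s,
             fo2 = fo2_dry * (1 - fh),
             fco2 = fco2_dry * (1 - fh),
             wvp_kpa = fh * bp)
}

#' Ambient (baseline) gas series
#'
#' Wet ambient fractions and vapor pressure seen during baseline slots.
#'
#' @inheritParams simulate_chamber_washout
#' @param n Number of 1 Hz samples (used when `env` is `NULL`).
#' @return data.frame: `time_s`, `fo2`, `fco2`, `wvp_kpa`.
#' @export
ambient_gas_series <- function(chamber, ambient = list(fio2 = 0.2095,
                                                       fico2 = 4e-4),
                               env = NULL, n = NULL) {
  if (is.null(env)) {
    stopifnot(!is.null(n))
    fh_a <- rep(0, n)
    t <- seq_len(n) - 1
  } else {
    fh_a <- pmin(env$rh / 100 * svp_kpa(env$temp_c) / chamber$bp_kpa, 0.1)
    t <- env$time_s
  }
  data.frame(time_s = t,
             fo2 = ambient$fio2 * (1 - fh_a),
             fco2 = ambient$fico2 * (1 - fh_a),
             wvp_kpa = fh_a * chamber$bp_kpa)
}

#' Simulate the multiplexed analyzer trace
#'
#' Switches the analyzer chain across chambers and the ambient baseline per
#' the sampling schedule, then applies (in order) a first-order analyzer
#' response, channel transport lags, slow linear span drift and additive
#' Gaussian noise. The marker channel records the active chamber (0 =
#' baseline). With zero noise, zero lags, zero drift and `response_tau_s = 0`
#' the output equals the switched true series sample for sample.
#'
#' @param chamber_traces Named list of per-chamber series from
#'   [simulate_chamber_washout()]; names are chamber ids.
#' @param ambient_trace Baseline series from [ambient_gas_series()].
#' @param schedule [sampling_schedule()].
#' @param analyzer [analyzer_model()].
#' @param chamber [chamber_config()] (flow and pressure columns).
#' @param seed RNG seed.
#' @return A gas trace data.frame: `time_s`, `fo2`, `fco2`, `wvp_kpa`,
#'   `bp_kpa`, `flow_ml_min`, `marker`.
#' @export
simulate_multiplexed_trace <- function(chamber_traces, ambient_trace,
                                       schedule, analyzer, chamber,
                                       seed = 1) {
  stopifnot(inherits(schedule, "sampling_schedule"),
            inherits(analyzer, "analyzer_model"))
  ids <- schedule$slots$chamber
  have <- suppressWarnings(as.integer(names(chamber_traces)))
  missing_ch <- setdiff(ids[ids != 0L], have)
  if (length(missing_ch))
    stop("schedule references nonexistent chamber(s): ",
         paste(missing_ch, collapse = ", "), call. = FALSE)

  n <- nrow(ambient_trace)
  marker <- rep(rep(ids, times = schedule$slots$dwell_s),
                length.out = n)
  fo2 <- ambient_trace$fo2
  fco2 <- ambient_trace$fco2
  wvp <- ambient_trace$wvp_kpa
  for (id in ids[ids != 0L]) {
    tr <- chamber_traces[[as.character(id)]]
    sel <- marker == id
    fo2[sel] <- tr$fo2[sel]
    fco2[sel] <- tr$fco2[sel]
    wvp[sel] <- tr$wvp_kpa[sel]
  }

  if (analyzer$response_tau_s > 0) {
    a <- exp(-1 / analyzer$response_tau_s)
    fo2 <- recursive_relax(fo2, a, fo2[1])
    fco2 <- recursive_relax(fco2, a, fco2[1])
    wvp <- recursive_relax(wvp, a, wvp[1])
  }

  delay <- function(x, lag) {
    lag <- as.integer(lag)
    if (lag == 0L) return(x)
    c(rep(x[1], lag), x[seq_len(length(x) - lag)])
  }
  fo2 <- delay(fo2, analyzer$lag_o2_s)
  fco2 <- delay(fco2, analyzer$lag_co2_h2o_s)
  wvp <- delay(wvp, analyzer$lag_co2_h2o_s)

  th <- (seq_len(n) - 1) / 3600
  fo2 <- fo2 + analyzer$drift_per_h[["fo2"]] * th
  fco2 <- fco2 + analyzer$drift_per_h[["fco2"]] * th
  wvp <- wvp + analyzer$drift_per_h[["wvp"]] * th

  set.seed(derive_seed(seed, 2L))
  if (analyzer$noise_sd[["fo2"]] > 0)
    fo2 <- fo2 + stats::rnorm(n, 0, analyzer$noise_sd[["fo2"]])
  if (analyzer$noise_sd[["fco2"]] > 0)
    fco2 <- fco2 + stats::rnorm(n, 0, analyzer$noise_sd[["fco2"]])
  if (analyzer$noise_sd[["wvp"]] > 0)
    wvp <- pmax(wvp + stats::rnorm(n, 0, analyzer$noise_sd[["wvp"]]), 0)

  data.frame(time_s = ambient_trace$time_s, fo2 = fo2, fco2 = fco2,
             wvp_kpa = wvp, bp_kpa = chamber$bp_kpa,
             flow_ml_min = chamber$flow_ml_min, marker = marker)
}

#' Simulate 1 Hz load-cell records
#'
#' Three channels (perch, food, water). The perch carries body mass while the
#' bird perches; food/water decrease by the consumed amounts during bouts;
#' refills add configured steps; the bird's mass appears on the food channel
#' on nights slept on the dish. Each channel drifts linearly (g/day) with the
#' accumulated drift reset at tare events, plus Gaussian 1 Hz noise. Negative
#' readings are clamped to zero with a warning count attribute.
#'
#' @param truth Output of [simulate_bird_rates()].
#' @param model [load_cell_model()].
#' @param body_mass_g Bird mass (g).
#' @param food_start_g,water_start_g Initial dish/bottle masses (g).
#' @param refills data.frame (`time_s`, `channel`, `amount_g`) or `NULL`.
#' @param tare_times Tare timestamps (s); default from the model's interval.
#' @param seed RNG seed.
#' @return data.frame `time_s`, `perch_g`, `food_g`, `water_g`; attributes
#'   `tare_times`, `n_clamped`.
#' @export
simulate_load_cells <- function(truth, model, body_mass_g = 27,
                                food_start_g = 60, water_start_g = 250,
                                refills = NULL, tare_times = NULL,
                                seed = 1) {
  stopifnot(inherits(model, "load_cell_model"))
  n <- nrow(truth)
  t <- truth$time_s
  if (is.null(tare_times))
    tare_times <- seq(0, t[n], by = model$tare_interval_days * 86400)
  if (!is.null(refills) && nrow(refills) &&
      (any(refills$time_s < t[1]) || any(refills$time_s > t[n])))
    stop("refill times outside the simulated span", call. = FALSE)

  drift <- function(rate_g_day) {
    last_tare <- tare_times[pmax(findInterval(t, tare_times), 1L)]
    rate_g_day * (t - last_tare) / 86400
  }
  step_series <- function(channel) {
    s <- numeric(n)
    if (is.null(refills)) return(s)
    r <- refills[refills$channel == channel, , drop = FALSE]
    for (i in seq_len(nrow(r)))
      s[t >= r$time_s[i]] <- s[t >= r$time_s[i]] + r$amount_g[i]
    s
  }

  perch <- body_mass_g * (truth$behavior == "perch") +
    drift(model$drift_perch_g_day)
  food <- food_start_g - truth$cum_food_g + step_series("food") +
    body_mass_g * (truth$behavior == "on_food_dish") +
    drift(model$drift_food_g_day)
  water <- water_start_g - truth$cum_water_g + step_series("water") +
    drift(model$drift_water_g_day)

  set.seed(derive_seed(seed, 3L))
  if (model$noise_sd_g > 0) {
    perch <- perch + stats::rnorm(n, 0, model$noise_sd_g)
    food <- food + stats::rnorm(n, 0, model$noise_sd_g)
    water <- water + stats::rnorm(n, 0, model$noise_sd_g)
  }
  n_clamped <- sum(perch < 0) + sum(food < 0) + sum(water < 0)
  if (n_clamped > 0)
    warning(sprintf("%d negative mass samples clamped to 0", n_clamped),
            call. = FALSE)
  out <- data.frame(time_s = t, perch_g = pmax(perch, 0),
                    food_g = pmax(food, 0), water_g = pmax(water, 0))
  attr(out, "tare_times") <- tare_times
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Simulate RFID body-temperature reads
#'
#' The antenna energizes the PIT tag every `read_period_s` seconds, but only
#' while the bird's behavior places it within antenna range (the ~13 cm range
#' modeled as a behavioral state gate).
#'
#' @param truth Output of [simulate_bird_rates()].
#' @param read_period_s Seconds between read attempts (default 2).
#' @param in_range_states Behaviors within antenna range.
#' @param tag Tag id string.
#' @return data.frame `time_s`, `tag`, `tb_c` (possibly empty).
#' @export
simulate_rfid_reads <- function(truth, read_period_s = 2,
                                in_range_states = "perch", tag = "TAG1") {
  assert_scalar_pos(read_period_s, "read_period_s")
  sel <- truth$time_s %% read_period_s == 0 &
    truth$behavior %in% in_range_states
  data.frame(time_s = truth$time_s[sel], tag = rep(tag, sum(sel)),
             tb_c = truth$body_temp_c[sel])
}

#' Simulate a full multiplexed experiment
#'
#' Runs the bird model for every configured bird, propagates each bird's gas
#' exchange through its chamber, multiplexes the analyzer chain, and produces
#' load-cell logs (including an empty reference chamber), RFID reads and the
#' environmental log — everything the processing pipeline consumes, plus the
#' ground truth.
#'
#' @param config [experiment_config()].
#' @param seed Master seed (overrides `config$seed` if given).
#' @return List: `truth` (per-bird), `gas` (multiplexed trace), `mass`
#'   (per-bird), `empty_mass`, `rfid` (per-bird), `env` (1-min log),
#'   `schedule`, `config`.
#' @export
simulate_experiment <- function(config = experiment_config(), seed = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  if (is.null(seed)) seed <- config$seed
  days <- config$days
  n <- as.integer(days * 86400)
  t <- seq_len(n) - 1

  env_1hz <- data.frame(
    time_s = t,
    temp_c = program_value(config$temperature, t, "linear"),
    rh = program_value(config$humidity, t, "linear"))
  env <- env_1hz[t %% 60 == 0, ]

  refills <- NULL
  if (!is.null(config$refill_every_days) && config$refill_every_days > 0 &&
      config$refill_every_days * 86400 < n) {
    rt <- seq(config$refill_every_days * 86400, n - 1,
              by = config$refill_every_days * 86400) +
      (config$lights_on_hour + 2) * 3600
    rt <- rt[rt < n]
    if (length(rt))
      refills <- data.frame(time_s = rep(rt, 2),
                            channel = rep(c("food", "water"),
                                          each = length(rt)),
                            amount_g = rep(c(config$refill_food_g,
                                             config$refill_water_g),
                                           each = length(rt)))
  }

  truth <- list(); chambers <- list(); mass <- list(); rfid <- list()
  for (b in seq_along(config$birds)) {
    p <- config$birds[[b]]
    tb <- simulate_bird_rates(p, days = days,
                              temperature = config$temperature,
                              humidity = config$humidity,
                              lights_on_hour = config$lights_on_hour,
                              lights_off_hour = config$lights_off_hour,
                              seed = derive_seed(seed, 100L + b))
    truth[[b]] <- tb
    chambers[[as.character(b)]] <-
      simulate_chamber_washout(tb, config$chamber, config$ambient, env_1hz)
    mass[[b]] <- simulate_load_cells(tb, config$load_cell,
                                     body_mass_g = p$body_mass_g,
                                     refills = refills,
                                     seed = derive_seed(seed, 200L + b))
    rfid[[b]] <- simulate_rfid_reads(tb, tag = sprintf("TAG%02d", b))
  }

  amb <- ambient_gas_series(config$chamber, config$ambient, env_1hz)
  gas <- simulate_multiplexed_trace(chambers, amb, config$schedule,
                                    config$analyzer, config$chamber,
                                    seed = derive_seed(seed, 300L))

  empty_truth <- truth[[1]]
  empty_truth$behavior <- "off_sensors"
  empty_truth$cum_food_g <- 0
  empty_truth$cum_water_g <- 0
  empty_mass <- simulate_load_cells(empty_truth, config$load_cell,
                                    body_mass_g = 0, refills = NULL,
                                    seed = derive_seed(seed, 400L))

  list(truth = truth, gas = gas, mass = mass, empty_mass = empty_mass,
       rfid = rfid, env = env, schedule = config$schedule, config = config)
}
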