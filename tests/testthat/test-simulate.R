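test_that("metabolic model reduces to bmr at thermoneutrality and follows the
           Scholander line below the lct", {
  p <- quiet_bird(bmr_ml_min = 1.2, conductance = 0.05, lct_c = 25,
                  activity_multiplier = 1)
  warm <- simulate_bird_rates(p, days = 0.1,
                              temperature = data.frame(time_s = 0,
                                                       temp_c = 30),
                              humidity = data.frame(time_s = 0, rh = 40),
                              seed = 1)
  expect_equal(unique(warm$true_vo2), 1.2)

  cold <- simulate_bird_rates(p, days = 0.1,
                              temperature = data.frame(time_s = 0,
                                                       temp_c = 15),
                              humidity = data.frame(time_s = 0, rh = 40),
                              seed = 1)
  # hand evaluation: 1.2 + 0.05 * (25 - 15) = 1.7
  expect_equal(unique(cold$true_vo2), 1.7)
  expect_equal(cold$true_vco2, cold$true_vo2 * p$rq)
})

test_that("bird simulation rejects non-finite parameters by name", {
  expect_error(bird_params(bmr_ml_min = NaN), "bmr_ml_min")
  expect_error(bird_params(lct_c = Inf), "lct_c")
})

test_that("chamber washout: steady-state outlet deficit equals VO2/flow and
           the step response is exactly exponential", {
  ch <- chamber_config()          # 13 L, 1700 ml/min
  tr <- constant_truth(7200)
  w <- simulate_chamber_washout(tr, ch, env = NULL)
  # mass balance: 1.7 / 1700 = 0.001 fraction units
  expect_equal(0.2095 - w$fo2[7200], 0.001, tolerance = 1e-10)

  # step in VO2 at t0: normalized response is 1 - exp(-t/tau) pointwise
  tr2 <- constant_truth(7200, vo2 = 0, vco2 = 0)
  tr2$true_vo2[3601:7200] <- 1.7
  w2 <- simulate_chamber_washout(tr2, ch, env = NULL)
  tau_s <- 60 * 13000 / 1700
  t_rel <- 0:3599
  resp <- (0.2095 - w2$fo2[3601:7200]) / 0.001
  # exact analytic update: after k 1-s steps the deficit is 1 - e^(-k/tau)
  expect_equal(resp, 1 - exp(-(t_rel + 1) / tau_s),
               tolerance = 1e-9, ignore_attr = TRUE)
  # 63.2% of the asymptotic change at t0 + tau
  expect_equal(resp[round(tau_s)], 1 - exp(-1), tolerance = 1e-3)

  # zero metabolism: outlet identical to ambient
  w3 <- simulate_chamber_washout(constant_truth(600, 0, 0, 0), ch,
                                 env = NULL)
  expect_equal(w3$fo2, rep(0.2095, 600))
  expect_equal(w3$wvp_kpa, rep(0, 600))
})

test_that("gas mass balance: flow-integrated deficit matches integrated VO2
           to better than 0.1% at steady state", {
  ch <- chamber_config()
  tr <- constant_truth(10000, vo2 = 1.4, vco2 = 1.19)
  w <- simulate_chamber_washout(tr, ch, env = NULL)
  win <- 5001:10000
  lhs <- sum((0.2095 - w$fo2[win]) * ch$flow_ml_min / 60)
  rhs <- sum(tr$true_vo2[win] / 60)
  expect_lt(abs(lhs - rhs) / rhs, 1e-3)
})

test_that("multiplexed trace: marker period, identity analyzer, and ambient
           baselines", {
  ch <- chamber_config()
  sched <- sampling_schedule(chambers = 1:7)
  expect_equal(sched$cycle_period_s, 480)   # one measurement per 8 min

  n <- 1920
  mk_tr <- function(level) data.frame(time_s = 0:(n - 1), fo2 = level,
                                      fco2 = 4e-4, wvp_kpa = 0)
  traces <- lapply(1:7, function(i) mk_tr(0.209 - i * 1e-4))
  names(traces) <- 1:7
  amb <- data.frame(time_s = 0:(n - 1), fo2 = 0.2095, fco2 = 4e-4,
                    wvp_kpa = 0)
  ident <- analyzer_model(lag_o2_s = 0, lag_co2_h2o_s = 0,
                          response_tau_s = 0,
                          noise_sd = c(fo2 = 0, fco2 = 0, wvp = 0),
                          drift_per_h = c(fo2 = 0, fco2 = 0, wvp = 0))
  g <- simulate_multiplexed_trace(traces, amb, sched, ident, ch, seed = 1)

  expect_equal(g$marker[1:480], g$marker[481:960])
  expect_setequal(unique(g$marker), 0:7)
  # identity analyzer reproduces the switched series sample for sample
  for (i in 1:7)
    expect_equal(unique(g$fo2[g$marker == i]), 0.209 - i * 1e-4)
  expect_equal(unique(g$fo2[g$marker == 0]), 0.2095)

  expect_error(
    simulate_multiplexed_trace(traces[1:3], amb,
                               sampling_schedule(chambers = 1:5),
                               ident, ch),
    "nonexistent chamber")
})

test_that("load cells: constancy without noise, refill steps, configured
           drift, and intake bookkeeping", {
  p <- quiet_bird()
  tr <- simulate_bird_rates(p, days = 1,
                            temperature = data.frame(time_s = 0, temp_c = 25),
                            humidity = data.frame(time_s = 0, rh = 40),
                            seed = 2)
  tr$behavior <- "off_sensors"; tr$cum_food_g <- 0; tr$cum_water_g <- 0

  quiet <- quiet_load_cell()
  m0 <- simulate_load_cells(tr, quiet, body_mass_g = 27)
  expect_equal(unique(m0$food_g), 60)
  expect_equal(unique(m0$water_g), 250)
  expect_equal(unique(m0$perch_g), 0)

  # refill is a single +150 g step on the water channel
  refs <- data.frame(time_s = 40000, channel = "water", amount_g = 150)
  m1 <- simulate_load_cells(tr, quiet, body_mass_g = 27, refills = refs)
  expect_equal(unique(m1$water_g[tr$time_s < 40000]), 250)
  expect_equal(unique(m1$water_g[tr$time_s >= 40000]), 400)

  # pure 0.5 g/day drift: empty-perch daily range is 0.5 g
  drifty <- load_cell_model(noise_sd_g = 0, drift_perch_g_day = 0.5,
                            drift_food_g_day = 0.04,
                            drift_water_g_day = 0.05,
                            tare_interval_days = 2)
  m2 <- simulate_load_cells(tr, drifty, body_mass_g = 0)
  expect_equal(max(m2$perch_g) - min(m2$perch_g), 0.5, tolerance = 1e-4)

  # cumulative simulated consumption equals the injected bout masses exactly
  tr2 <- simulate_bird_rates(quiet_bird(), days = 1, seed = 5)
  bouts <- attr(tr2, "bouts")
  expect_equal(max(tr2$cum_food_g),
               sum(bouts$mass_g[bouts$channel == "food"]))
  expect_equal(max(tr2$cum_water_g),
               sum(bouts$mass_g[bouts$channel == "water"]))
})

test_that("RFID reads: cadence, range gating and temperature pass-through", {
  p <- quiet_bird()
  tr <- simulate_bird_rates(p, days = 0.05,
                            temperature = data.frame(time_s = 0, temp_c = 25),
                            humidity = data.frame(time_s = 0, rh = 40),
                            seed = 1)
  tr$behavior <- "perch"
  tr$body_temp_c <- 41.0
  r <- simulate_rfid_reads(tr, read_period_s = 2)
  # perched for the whole span, read every 2 s: 30 reads per minute
  expect_equal(nrow(r), nrow(tr) / 2)
  expect_equal(unique(r$tb_c), 41.0)

  tr$behavior <- "off_sensors"
  expect_equal(nrow(simulate_rfid_reads(tr, 2)), 0)
  # empty in-range set is an empty log, not an error
  expect_equal(nrow(simulate_rfid_reads(tr, 2, in_range_states = character())),
               0)
})

test_that("fixed seed gives bit-identical simulations", {
  cfg <- experiment_config(days = 0.2, seed = 7)
  a <- suppressWarnings(simulate_experiment(cfg, seed = 7))
  b <- suppressWarnings(simulate_experiment(cfg, seed = 7))
  expect_identical(a$gas, b$gas)
  expect_identical(a$mass, b$mass)
  expect_identical(a$truth, b$truth)
})
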