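test_that("load-cell calibration recovers the counts-to-grams line", {
  # two-point calibration: 0 counts = 0 g, 1000 counts = 100 g
  cal <- calibrate_load_cell(c(0, 1000), c(0, 100))
  expect_equal(cal$scale, 0.1)
  expect_equal(cal$offset, 0, tolerance = 1e-12)

  set.seed(11)
  ref <- seq(25, 200, by = 25)
  counts <- (ref + rnorm(8, 0, 0.05)) / 0.097
  cal2 <- calibrate_load_cell(counts, ref)
  expect_lt(abs(cal2$scale - 0.097) / 0.097, 0.005)

  expect_error(calibrate_load_cell(c(1, 2), c(50, 50)), "distinct")
})

test_that("stable-point selection keeps one minimum-SD rolling mean per
           10-minute block", {
  t <- 0:3599
  s <- stable_point_selection(t, rep(27, 3600))
  expect_equal(nrow(s), 6)           # 3600 s / 600 s blocks
  expect_equal(s$value_g, rep(27, 6))
  expect_equal(s$sd_g, rep(0, 6))

  # quiet first half, noisy second half: the point comes from the quiet half
  set.seed(4)
  x <- c(rep(27, 300), 27 + rnorm(300, 0, 0.5))
  s2 <- stable_point_selection(0:599, x)
  expect_equal(nrow(s2), 1)
  expect_lt(s2$time_s, 300)
  expect_equal(s2$value_g, 27)

  expect_equal(nrow(stable_point_selection(numeric(), numeric())), 0)
})

test_that("lag differences propagate error and reject 3-SD outliers", {
  # sds 3 and 4 propagate to 5
  p <- data.frame(time_s = c(0, 600), value_g = c(10, 12), sd_g = c(3, 4))
  ev <- lag_difference_filter(p)
  expect_equal(ev$sd_delta_g, 5)
  expect_equal(ev$delta_g, 2)

  # 100 unit-scale deltas plus one far outlier: exactly the spike rejected
  set.seed(8)
  d <- rnorm(100, 0, 0.5)
  d[50] <- 10 * sd(d)
  pts <- data.frame(time_s = (0:100) * 600, value_g = cumsum(c(0, d)),
                    sd_g = 0)
  ev2 <- lag_difference_filter(pts, exclude_threshold = Inf)
  expect_equal(which(ev2$class == "rejected_outlier"), 50)

  # all deltas identical: zero dispersion, nothing rejected
  pts3 <- data.frame(time_s = (0:10) * 600, value_g = (0:10) * 0.5, sd_g = 0)
  expect_true(all(is.na(lag_difference_filter(pts3)$class)))

  # a single point yields an empty event list
  expect_equal(nrow(lag_difference_filter(pts3[1, ])), 0)
})

test_that("3-SD rule rejects Gaussian-only deltas at roughly the nominal
           0.3%-per-point rate", {
  hits <- vapply(1:50, function(s) {
    set.seed(s)
    pts <- data.frame(time_s = (0:100) * 600,
                      value_g = cumsum(c(27, rnorm(100, 0, 0.05))), sd_g = 0)
    sum(lag_difference_filter(pts)$class == "rejected_outlier", na.rm = TRUE)
  }, numeric(1))
  expect_lt(mean(hits) / 100, 0.01)   # per-point false rejection under 1%
  expect_gt(mean(hits == 0), 0.6)     # most runs lose nothing
})

test_that("event classification fires exactly at the 20 g and 35 g
           thresholds", {
  mk <- function(delta) data.frame(time_s = 0, delta_g = delta,
                                   sd_delta_g = 0.01, class = NA_character_)
  cl <- function(delta, ch = "food")
    classify_mass_events(mk(delta), ch)$class

  expect_equal(cl(+150), "refill")
  expect_equal(cl(-27), "body_mass_recode")
  expect_equal(cl(-0.3), "consumption")
  # boundaries: the refill/recode band is (20, 35]
  expect_equal(cl(20), "consumption")
  expect_equal(cl(20.0001), "body_mass_recode")
  expect_equal(cl(35), "body_mass_recode")
  expect_equal(cl(-35.0001), "refill")
  # recode recovers |delta| as the mass, with the step direction
  r <- classify_mass_events(mk(-27), "water")
  expect_equal(r$mass_g, 27)
  expect_equal(r$direction, "-")
  # perch channel is never recoded
  expect_equal(cl(-27, "perch"), "perch_step")
})

test_that("intake aggregation sums consumption and averages mass points", {
  ev <- data.frame(time_s = seq(300, 3300, by = 600), delta_g = -0.5,
                   sd_delta_g = 0.01, class = "consumption",
                   mass_g = NA_real_, direction = NA_character_)
  empty <- ev[0, ]
  pp <- data.frame(time_s = c(600, 1800), value_g = c(26.8, 27.2),
                   sd_g = 0.01)
  agg <- aggregate_intake(ev, empty, pp, "hour", span_s = c(0, 3600))
  expect_equal(agg$food_g, 3.0)      # six -0.5 g deltas
  expect_equal(agg$mass_g, 27.0)

  # empty bin: zero intake but missing mass
  agg2 <- aggregate_intake(empty, empty, pp[0, ], "hour",
                           span_s = c(0, 3600))
  expect_equal(agg2$food_g, 0)
  expect_true(is.na(agg2$mass_g))

  # recoded body-mass events contribute to the bin mass
  rec <- data.frame(time_s = 1200, delta_g = -27, sd_delta_g = 0.01,
                    class = "body_mass_recode", mass_g = 27,
                    direction = "-")
  agg3 <- aggregate_intake(rec, empty, pp[0, ], "hour", span_s = c(0, 3600))
  expect_equal(agg3$mass_g, 27)
})

test_that("daily sensor drift is the max-minus-min of stable points", {
  const <- data.frame(time_s = c(0, 40000), value_g = 27, sd_g = 0)
  expect_equal(sensor_drift(const)$drift_g, 0)

  # sawtooth of amplitude 0.2 g
  t <- seq(0, 86399, by = 600)
  saw <- data.frame(time_s = t, value_g = 0.2 * abs(2 * ((t / 7200) %% 1) - 1),
                    sd_g = 0)
  expect_equal(sensor_drift(saw)$drift_g, 0.2, tolerance = 0.01)
})

test_that("intake conservation: zero sensor noise recovers simulated
           consumption exactly", {
  p <- quiet_bird()
  tr <- simulate_bird_rates(p, days = 1,
                            temperature = data.frame(time_s = 0, temp_c = 25),
                            humidity = data.frame(time_s = 0, rh = 40),
                            seed = 6)
  m <- simulate_load_cells(tr, quiet_load_cell(), body_mass_g = 27)
  res <- process_mass_trace(m)
  expect_equal(sum(res$hourly$food_g), max(tr$cum_food_g), tolerance = 1e-8)
  expect_equal(sum(res$hourly$water_g), max(tr$cum_water_g),
               tolerance = 1e-8)
})

test_that("dish-sleeping nights are rescued as body-mass measurements", {
  p <- bird_params(p_sleep_on_dish = 1, body_mass_g = 27)
  tr <- simulate_bird_rates(p, days = 2,
                            temperature = data.frame(time_s = 0, temp_c = 25),
                            humidity = data.frame(time_s = 0, rh = 40),
                            seed = 13)
  m <- simulate_load_cells(tr, load_cell_model(), body_mass_g = 27,
                           seed = 13)
  res <- process_mass_trace(m)
  rec <- res$events$food[res$events$food$class == "body_mass_recode", ]
  expect_gte(nrow(rec), 2)
  expect_true(all(abs(rec$mass_g - 27) < 0.5))
})
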