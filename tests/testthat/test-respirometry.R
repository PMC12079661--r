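test_that("time constant and washout fraction analytics", {
  expect_equal(time_constant(1, 1000), 1)
  expect_equal(time_constant(13, 1700), 13000 / 1700)  # 7.647 min
  expect_equal(time_constant(13, 2000), 6.5)
  expect_error(time_constant(0, 1700), "volume")

  expect_equal(washout_fraction(0, 100), 0)
  expect_equal(washout_fraction(100, 100), 1 - exp(-1))
  expect_equal(washout_fraction(300, 100), 1 - exp(-3))
  expect_error(washout_fraction(-1, 100), ">= 0")
  expect_error(washout_fraction(1, 0), "tau")
})

test_that("lag alignment shifts channels onto the marker clock", {
  n <- 200
  tr <- data.frame(time_s = 0:(n - 1), fo2 = 0, fco2 = 0, wvp_kpa = 0,
                   bp_kpa = 101.3, flow_ml_min = 1700, marker = 1L)
  expect_equal(lag_align(tr, 0, 0), tr)

  tr$fo2[101] <- 1   # impulse at t = 100
  al <- lag_align(tr, 7, 5)
  expect_equal(al$time_s[which(al$fo2 == 1)], 93)
  expect_equal(nrow(al), n - 7)
  expect_error(lag_align(tr, n, 5), "exceeds")

  # built-in 7 s / 5 s delays cross-correlate at zero offset after alignment
  set.seed(42)
  sig <- cumsum(rnorm(500))
  tr2 <- data.frame(time_s = 0:491,
                    fo2 = sig[(1:492) + 0],       # delayed 7 relative to truth
                    fco2 = sig[(1:492) + 2],      # delayed 5
                    wvp_kpa = sig[(1:492) + 2],
                    bp_kpa = 101.3, flow_ml_min = 1700, marker = 1L)
  al2 <- lag_align(tr2, 7, 5)
  cc <- ccf(al2$fo2, al2$fco2, lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("instantaneous correction inverts first-order washout", {
  expect_equal(instantaneous_correct(rep(5, 100), tau_s = 50), rep(5, 100))

  tau <- 458.8
  t <- 0:599
  f <- 0.21 * (1 - exp(-t / tau))
  corr <- instantaneous_correct(f, tau, smoothing_window_s = 5)
  interior <- 10:590
  expect_lt(max(abs(corr[interior] - 0.21)) / 0.21, 0.005)

  # step through a simulated first-order chamber recovers within 1% after
  # a few samples
  tr <- constant_truth(1200, vo2 = 0)
  tr$true_vo2[301:1200] <- 1.7
  w <- simulate_chamber_washout(tr, chamber_config(), env = NULL)
  z <- instantaneous_correct(w$fo2, 60 * 13000 / 1700,
                             smoothing_window_s = 5)
  vo2_hat <- (0.2095 - z) * 1700
  expect_lt(max(abs(vo2_hat[306:1190] - 1.7)) / 1.7, 0.01)

  expect_error(instantaneous_correct(c(1, 2), 10, smoothing_window_s = 5),
               "shorter")
})

test_that("stable-window extraction picks the minimum-SD 15 s segment of the
           final 30 s", {
  mk_trace <- function(fo2_win, chamber = 1L) {
    n <- length(fo2_win)
    pre <- rep(fo2_win[1], 60 - n %% 60)
    x <- c(pre, fo2_win)
    data.frame(time_s = seq_along(x) - 1, fo2 = x, fco2 = 4e-4,
               wvp_kpa = 0, bp_kpa = 101.3, flow_ml_min = 1700,
               marker = chamber)
  }
  sched <- sampling_schedule(chambers = 1L)

  # constant window: mean is the constant, earliest segment chosen
  tr <- mk_trace(rep(0.208, 60))
  w <- extract_stable_windows(tr, sched)
  expect_equal(w$fo2, 0.208)
  expect_equal(w$seg_start_s, tr$time_s[nrow(tr)] - 29)

  # flat first half of the final 30 s, then a ramp: the flat half is selected
  fin <- c(rep(0.208, 15), 0.208 + seq_len(15) * 1e-4)
  tr2 <- mk_trace(c(rep(0.208, 30), fin))
  w2 <- extract_stable_windows(tr2, sched)
  expect_equal(w2$fo2, 0.208)
  expect_equal(w2$sd_fo2, 0)

  # property: function agrees with a brute-force scan on noisy windows
  set.seed(9)
  for (i in 1:5) {
    fin <- 0.208 + rnorm(30, 0, 1e-4)
    tr3 <- mk_trace(c(rep(0.208, 30), fin))
    w3 <- extract_stable_windows(tr3, sched)
    sds <- vapply(1:16, function(k) sd(fin[k:(k + 14)]), numeric(1))
    k_best <- which.min(sds)
    expect_equal(w3$fo2, mean(fin[k_best:(k_best + 14)]))
    # cumulative-sum variance agrees with stats::sd to ~8 digits here
    expect_equal(w3$sd_fo2, sds[k_best], tolerance = 1e-6)
  }

  expect_error(extract_stable_windows(tr, sampling_schedule(1L, dwell_s = 20)),
               "dwell")
})

test_that("baseline correction interpolates ambient linearly and removes
           affine drift exactly", {
  base <- data.frame(time_s = c(0, 480), fo2 = c(0.2090, 0.2094))
  smp <- data.frame(time_s = 240, chamber = 1L, fo2 = 0.2082)
  d <- baseline_correct(smp, base, channels = "fo2")
  expect_equal(d$d_fo2, -0.0010)

  # identical baselines: constant subtraction
  base2 <- data.frame(time_s = c(0, 480), fo2 = c(0.209, 0.209))
  d2 <- baseline_correct(data.frame(time_s = 100, fo2 = 0.21), base2,
                         channels = "fo2")
  expect_equal(d2$d_fo2, 0.001)

  # arbitrary affine analyzer drift with zero metabolism: deltas exactly 0
  drift <- function(t) 0.2090 + 3e-7 * t
  bt <- seq(0, 4800, by = 480)
  st <- bt[-1] - 240
  d3 <- baseline_correct(data.frame(time_s = st, fo2 = drift(st)),
                         data.frame(time_s = bt, fo2 = drift(bt)),
                         channels = "fo2")
  expect_equal(d3$d_fo2, rep(0, length(st)), tolerance = 1e-15)

  expect_error(baseline_correct(smp, base[0, ], channels = "fo2"),
               "no baseline")
})

test_that("water-vapor dilution correction and its round trip", {
  expect_equal(water_vapor_correct(0.2079, 4e-4, 0, 101.3)$fo2_dry, 0.2079)
  w <- water_vapor_correct(0.2079, 4e-4, 1.013, 101.3, flow_ml_min = 1700)
  expect_equal(w$fo2_dry, 0.21)
  expect_equal(w$flow_dry, 1683)

  # round trip to machine precision
  wet <- 0.207; wvp <- 2.4; bp <- 101.3
  dry <- water_vapor_correct(wet, 1e-3, wvp, bp)
  expect_equal(dry$fo2_dry * (1 - wvp / bp), wet, tolerance = 1e-15)

  expect_error(water_vapor_correct(0.2, 1e-3, 102, 101.3), "wvp")
})

test_that("pull-mode exchange equations match hand evaluation", {
  d0 <- data.frame(time_s = 0, chamber = 1L, d_fo2_dry = 0, d_fco2_dry = 0,
                   d_wvp_kpa = 0, flow_dry = 1700, flow_ml_min = 1700,
                   bp_kpa = 101.3)
  r0 <- compute_exchange_rates(d0)
  expect_equal(c(r0$vo2_ml_min, r0$vco2_ml_min, r0$vh2o_mg_min), c(0, 0, 0))

  # FiO2 deficit 0.001 and FeCO2 excess 0.00085 at 1700 ml/min dry flow
  d1 <- d0
  d1$d_fo2_dry <- -0.001; d1$d_fco2_dry <- 0.00085; d1$d_wvp_kpa <- 0.111
  r1 <- compute_exchange_rates(d1)
  expect_equal(r1$vo2_ml_min, 1.7, tolerance = 1e-7)
  expect_equal(r1$vco2_ml_min, 1.445, tolerance = 1e-7)
  # VH2O: 1700 * 0.111/101.3 ml vapor -> mg at 22414 ml/mol, 18.02 g/mol
  expect_equal(r1$vh2o_mg_min, 1700 * 0.111 / 101.3 / (22414 / 18020),
               tolerance = 1e-10)

  d2 <- d1; d2$d_fo2_dry <- NA
  expect_error(compute_exchange_rates(d2), "non-finite")
})
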