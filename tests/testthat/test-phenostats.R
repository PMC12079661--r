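test_that("hourly table joins on the shared clock and flags lights-off
           hours", {
  mk_energy <- function(hours) data.frame(
    bin_start_s = hours * 3600, o2_ml = 90, co2_ml = 75,
    h2o_mg = 100, ee_kj = 2, vh2o_mg_min = 1.6, n_points = 15,
    coverage = 1, flagged = FALSE)
  mk_intake <- function(hours) data.frame(
    bin_start_s = hours * 3600, food_g = 0.4, water_g = 0.8,
    mass_g = 27, n_mass = 5)
  env <- data.frame(time_s = seq(0, 48 * 3600 - 60, by = 60), temp_c = 20,
                    rh = 45)

  tab <- build_hourly_table(list(`1` = mk_energy(0:47)),
                            list(`1` = mk_intake(0:47)), env)
  expect_equal(nrow(tab), 48)
  expect_equal(sum(tab$lights), 24)    # 12:12 photoperiod
  expect_equal(unique(tab$temp_c), 20)

  # disjoint hours produce an empty join
  empty <- build_hourly_table(list(`1` = mk_energy(0:5)),
                              list(`1` = mk_intake(40:45)), env)
  expect_equal(nrow(empty), 0)
})

test_that("all-subsets AIC selection behaves on known designs", {
  set.seed(21)
  n <- 120
  d <- data.frame(temp = runif(n, 5, 25), z = runif(n))
  d$y <- 2 - 0.05 * d$temp + rnorm(n, 0, 0.02)

  fit <- fit_model_set(d, "y", c("temp", "z"))
  expect_true(grepl("temp", fit$selected_formula))
  ci <- confint(fit$selected, "temp")
  expect_true(ci[1] < -0.05 && -0.05 < ci[2])
  # AIC ordering is returned and the selected model has minimal AIC
  expect_equal(fit$fits$aic, sort(fit$fits$aic))

  # intercept-only wins for pure noise in most seeded replicates
  wins <- vapply(1:100, function(s) {
    set.seed(s)
    dd <- data.frame(x = runif(40), y = rnorm(40))
    fit_model_set(dd, "y", "x")$selected_formula == "y ~ 1"
  }, logical(1))
  expect_gte(mean(wins), 0.8)

  # perfectly collinear duplicate predictor is an error
  d$temp2 <- d$temp
  expect_error(fit_model_set(d, "y", c("temp", "temp2")), "rank-deficient")
})

test_that("AIC selection is invariant to predictor ordering", {
  set.seed(5)
  d <- data.frame(a = rnorm(80), b = rnorm(80))
  d$y <- 1 + 0.5 * d$a + rnorm(80, 0, 0.3)
  f1 <- fit_model_set(d, "y", c("a", "b"))
  f2 <- fit_model_set(d, "y", c("b", "a"))
  expect_equal(sort(f1$fits$aic), sort(f2$fits$aic))
  expect_equal(AIC(f1$selected), AIC(f2$selected))
})

test_that("percent effect back-transforms log-scale coefficients", {
  expect_equal(percent_effect(0), 0)
  expect_equal(percent_effect(log(1.05)), 5)
  expect_equal(percent_effect(log(1.17)), 17)
  expect_equal(percent_effect(log(0.96)), -4)
})

test_that("log transform drops non-positive responses with a message", {
  d <- data.frame(x = 1:10, y = c(-1, 0, 3:10))
  expect_message(fit <- fit_model_set(d, "y", "x", log_response = TRUE),
                 "non-positive")
  expect_equal(stats::nobs(fit$selected), 8)
})
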