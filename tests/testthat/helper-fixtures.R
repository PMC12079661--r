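# Shared fixtures. The reference experiment (3 birds, 10 days, 25->5 degC)
# is expensive, so it is built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

# Analyzer / load-cell models with every stochastic term switched off.
quiet_analyzer <- function() {
  analyzer_model(noise_sd = c(fo2 = 0, fco2 = 0, wvp = 0),
                 drift_per_h = c(fo2 = 0, fco2 = 0, wvp = 0))
}
quiet_load_cell <- function() {
  load_cell_model(noise_sd_g = 0, drift_perch_g_day = 0,
                  drift_food_g_day = 0, drift_water_g_day = 0)
}

# A bird with all physiological noise disabled (deterministic truth).
quiet_bird <- function(...) {
  bird_params(pn_vo2_sd = 0, pn_ewl_sd = 0, intake_noise_sd = 0,
              p_sleep_on_dish = 0, ...)
}

# Reference study: the default acute cold-acclimation design, seed 1.
reference_run <- function() {
  if (is.null(.fixture_env$ref)) {
    .fixture_env$ref <- suppressWarnings(
      run_experiment(experiment_config(seed = 1), seed = 1))
  }
  .fixture_env$ref
}

# Constant-rate truth series (1 Hz) for washout tests.
constant_truth <- function(n, vo2 = 1.7, vco2 = 1.445, vh2o = 0) {
  data.frame(time_s = seq_len(n) - 1, true_vo2 = rep(vo2, n),
             true_vco2 = rep(vco2, n), true_vh2o = rep(vh2o, n))
}
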