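# End-to-end glue: simulated (or read) streams -> metabolic points ->
# hourly energetics -> intake/mass -> hourly phenotype table -> model fits.

#' Run the full phenotyping pipeline on an experiment
#'
#' Processes the multiplexed gas trace into per-chamber metabolic points,
#' integrates them into hourly energetics, runs the load-cell pipeline per
#' bird, and joins everything into the hourly phenotype table. Input is
#' either the list returned by [simulate_experiment()] or an equivalent list
#' assembled from files read with the `read_*` functions.
#'
#' @param sim List with `gas`, `mass` (per-bird list), `env`, `schedule`,
#'   `config`.
#' @return List: `points` (all chambers), `energy_hourly` / `energy_daily`
#'   (per bird), `mass` (per-bird [process_mass_trace()] results), `hourly`
#'   (phenotype table), `min_mr` (per-bird daily minimum metabolic rate).
#' @export
run_pipeline <- function(sim) {
  cfg <- sim$config
  points <- process_gas_trace(sim$gas, sim$schedule, cfg$chamber,
                              cfg$analyzer)
  birds <- as.character(seq_along(sim$mass))
  energy_h <- lapply(birds, function(b)
    integrate_rates(points[points$chamber == as.integer(b), ], "hour",
                    cfg$thresholds$coverage_min))
  energy_d <- lapply(birds, function(b)
    integrate_rates(points[points$chamber == as.integer(b), ], "day",
                    cfg$thresholds$coverage_min))
  names(energy_h) <- names(energy_d) <- birds

  massres <- lapply(sim$mass, process_mass_trace,
                    thresholds = cfg$thresholds)
  names(massres) <- birds
  intake_h <- lapply(massres, `[[`, "hourly")

  hourly <- build_hourly_table(energy_h, intake_h, sim$env,
                               cfg$lights_on_hour, cfg$lights_off_hour)
  min_mr <- lapply(birds, function(b)
    daily_min_mr(points[points$chamber == as.integer(b), ]))
  names(min_mr) <- birds

  list(points = points, energy_hourly = energy_h, energy_daily = energy_d,
       mass = massres, hourly = hourly, min_mr = min_mr)
}

#' Simulate, process and fit in one call
#'
#' Convenience wrapper: [simulate_experiment()], [run_pipeline()] and
#' [fit_paper_models()] back to back.
#'
#' @param config [experiment_config()].
#' @param seed Master seed.
#' @return List: `sim`, `pipeline`, `fits`.
#' @export
run_experiment <- function(config = experiment_config(), seed = NULL) {
  sim <- simulate_experiment(config, seed)
  pl <- run_pipeline(sim)
  fits <- fit_paper_models(pl$hourly)
  list(sim = sim, pipeline = pl, fits = fits)
}
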