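# Hourly phenotype table and the linear-model layer: log transforms,
# all-subsets AIC selection, nighttime exclusion for intake models, and
# percent-effect back-transformation.

#' Build the per-bird hourly phenotype table
#'
#' Joins hourly energy expenditure and water loss (from [integrate_rates()]),
#' hourly intake and body mass (from [process_mass_trace()]) and hourly
#' environmental means on the shared experiment clock, one row per bird-hour,
#' flagging lights-off hours (excluded from the intake models).
#'
#' @param energy Named list (bird id -> hourly [integrate_rates()] output).
#' @param intake Named list (bird id -> hourly [aggregate_intake()] output).
#' @param env Environment log data.frame (`time_s`, `temp_c`, `rh`).
#' @param lights_on_hour,lights_off_hour Photophase bounds (clock hours).
#' @return data.frame: `bird`, `hour` (experiment hour index), `hod`
#'   (hour-of-day factor), `temp_c`, `rh`, `ee_kj`, `vh2o_mg_min`, `food_g`,
#'   `water_g`, `mass_g`, `lights`, `ee_flagged`.
#' @export
build_hourly_table <- function(energy, intake, env, lights_on_hour = 7,
                               lights_off_hour = 19) {
  ehr <- floor(env$time_s / 3600)
  env_h <- data.frame(hour = sort(unique(ehr)),
                      temp_c = as.numeric(tapply(env$temp_c, ehr, mean)),
                      rh = as.numeric(tapply(env$rh, ehr, mean)))
  rows <- lapply(names(energy), function(b) {
    e <- energy[[b]]
    i <- intake[[b]]
    he <- floor(e$bin_start_s / 3600)
    hi <- floor(i$bin_start_s / 3600)
    common <- intersect(intersect(he, hi), env_h$hour)
    if (!length(common)) return(NULL)
    e <- e[match(common, he), ]
    i <- i[match(common, hi), ]
    ev <- env_h[match(common, env_h$hour), ]
    data.frame(bird = b, hour = common, hod = common %% 24,
               temp_c = ev$temp_c, rh = ev$rh,
               ee_kj = e$ee_kj, vh2o_mg_min = e$vh2o_mg_min,
               food_g = i$food_g, water_g = i$water_g, mass_g = i$mass_g,
               lights = (common %% 24) >= lights_on_hour &
                 (common %% 24) < lights_off_hour,
               ee_flagged = e$flagged)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(bird = character(), hour = integer(),
                      hod = integer(), temp_c = numeric(), rh = numeric(),
                      ee_kj = numeric(), vh2o_mg_min = numeric(),
                      food_g = numeric(), water_g = numeric(),
                      mass_g = numeric(), lights = logical(),
                      ee_flagged = logical()))
  out$bird <- factor(out$bird)
  out$hod <- factor(out$hod)
  rownames(out) <- NULL
  out
}

#' Fit all predictor subsets and select by AIC
#'
#' Least-squares fits of every subset of the candidate predictors (including
#' the intercept-only model), ordered by AIC; the minimum-AIC model is
#' selected. A rank-deficient full design (e.g. perfectly collinear
#' predictors) is an error, not silently dropped.
#'
#' @param table Data frame (e.g. from [build_hourly_table()]).
#' @param response Response column name.
#' @param predictors Candidate predictor column names.
#' @param log_response Log-transform the response (rows with non-positive
#'   response are dropped with a message).
#' @return List: `fits` (data.frame of formula/AIC/df, AIC-ordered),
#'   `selected` (the minimum-AIC `lm`), `selected_formula`.
#' @export
fit_model_set <- function(table, response, predictors,
                          log_response = FALSE) {
  stopifnot(all(c(response, predictors) %in% names(table)))
  dat <- table[stats::complete.cases(table[c(response, predictors)]), ]
  lhs <- response
  if (log_response) {
    bad <- dat[[response]] <= 0
    if (any(bad)) {
      message(sprintf("dropping %d non-positive responses before log",
                      sum(bad)))
      dat <- dat[!bad, ]
    }
    lhs <- sprintf("log(%s)", response)
  }
  full <- stats::lm(stats::as.formula(
    paste(lhs, "~", paste(predictors, collapse = " + "))), data = dat)
  if (any(is.na(stats::coef(full))))
    stop("rank-deficient design: collinear predictors", call. = FALSE)

  subsets <- unlist(lapply(0:length(predictors), function(k)
    utils::combn(predictors, k, simplify = FALSE)), recursive = FALSE)
  fits <- lapply(subsets, function(p) {
    rhs <- if (length(p)) paste(p, collapse = " + ") else "1"
    stats::lm(stats::as.formula(paste(lhs, "~", rhs)), data = dat)
  })
  aics <- vapply(fits, stats::AIC, numeric(1))
  tab <- data.frame(
    formula = vapply(fits, function(f) deparse(stats::formula(f)),
                     character(1)),
    aic = aics,
    n_pred = vapply(subsets, length, integer(1)))
  o <- order(aics)
  best <- fits[[o[1]]]
  list(fits = tab[o, ], selected = best,
       selected_formula = tab$formula[o][1])
}

#' Percent effect from a log-scale coefficient
#'
#' For a model with log response, a coefficient `beta` corresponds to a
#' `100 * (exp(beta) - 1)` percent change in the response per unit of the
#' predictor.
#'
#' @param beta Coefficient on the log scale.
#' @return Percent change per unit predictor.
#' @export
percent_effect <- function(beta) 100 * expm1(beta)

#' Fit the standard hourly phenotype models
#'
#' The four models of the analysis layer, fitted by least squares on the
#' hourly table (flagged EE bins dropped; intake models restricted to
#' lights-on hours):
#' \itemize{
#'   \item EE (kJ) ~ temperature + hour-of-day + bird
#'   \item log(VH2O) ~ temperature + RH + hour-of-day + bird
#'   \item food (g) ~ EE + bird (lights-on)
#'   \item log(water) ~ EE + hour-of-day (lights-on)
#' }
#'
#' @param table [build_hourly_table()] output.
#' @param conf_level Confidence level for the coefficient intervals.
#' @return List of `lm` fits (`ee`, `vh2o`, `food`, `water`) plus
#'   `coefficients`: a data.frame with the slope of interest for each model
#'   (`estimate`, `ci_lo`, `ci_hi`, and the percent back-transforms where the
#'   response is logged).
#' @export
fit_paper_models <- function(table, conf_level = 0.95) {
  d <- table[!table$ee_flagged & is.finite(table$ee_kj), ]
  day <- d[d$lights & is.finite(d$food_g) & is.finite(d$water_g), ]

  ee <- stats::lm(ee_kj ~ temp_c + hod + bird, data = d)
  vh2o <- stats::lm(log(vh2o_mg_min) ~ temp_c + rh + hod + bird,
                    data = d[d$vh2o_mg_min > 0, ])
  food <- stats::lm(food_g ~ ee_kj + bird, data = day)
  water <- stats::lm(log(water_g) ~ ee_kj + hod,
                     data = day[day$water_g > 0, ])

  row_of <- function(fit, term, pct = FALSE) {
    est <- stats::coef(fit)[[term]]
    ci <- stats::confint(fit, term, level = conf_level)
    out <- data.frame(term = term, estimate = est, ci_lo = ci[1],
                      ci_hi = ci[2])
    if (pct) {
      out$pct <- percent_effect(est)
      out$pct_lo <- percent_effect(ci[1])
      out$pct_hi <- percent_effect(ci[2])
    } else out$pct <- out$pct_lo <- out$pct_hi <- NA_real_
    out
  }
  coefs <- rbind(
    cbind(model = "ee", row_of(ee, "temp_c")),
    cbind(model = "vh2o_temp", row_of(vh2o, "temp_c", pct = TRUE)),
    cbind(model = "vh2o_rh", row_of(vh2o, "rh", pct = TRUE)),
    cbind(model = "food", row_of(food, "ee_kj")),
    cbind(model = "water", row_of(water, "ee_kj", pct = TRUE)))
  rownames(coefs) <- NULL
  list(ee = ee, vh2o = vh2o, food = food, water = water,
       coefficients = coefs)
}
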