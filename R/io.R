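# Readers and writers for the stream formats: Arduino load-cell logs,
# gas-trace CSV, RFID CSV, metabolic-point / hourly CSV, and YAML
# experiment configuration. All writers and readers are mutual inverses on
# their own output.

#' Write / read an Arduino load-cell log
#'
#' Canonical text layout: comma-delimited `time_s,perch_g,food_g,water_g`
#' with a header row; tare resets are metadata lines `#TARE <time_s>`.
#' Unparseable rows are skipped with a warning (more than 10% skipped is an
#' error); gaps in the 1 Hz cadence are reported in the `gaps` attribute.
#'
#' @param trace Mass trace data.frame (`time_s`, `perch_g`, `food_g`,
#'   `water_g`), tare times in the `tare_times` attribute.
#' @param path File path.
#' @return `write_arduino_log`: the path, invisibly. `read_arduino_log`: the
#'   mass trace with `tare_times`, `n_skipped` and `gaps` attributes.
#' @export
write_arduino_log <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  tt <- attr(trace, "tare_times")
  if (!is.null(tt))
    writeLines(sprintf("#TARE %s", format(tt, scientific = FALSE)), con)
  writeLines("time_s,perch_g,food_g,water_g", con)
  utils::write.table(data.frame(trace$time_s,
                                round(trace$perch_g, 4),
                                round(trace$food_g, 4),
                                round(trace$water_g, 4)),
                     con, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_arduino_log
#' @export
read_arduino_log <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  tare_times <- as.numeric(sub("^#TARE\\s+", "",
                               grep("^#TARE", lines, value = TRUE)))
  lines <- lines[!grepl("^#", lines)]
  if (length(lines) && grepl("^[A-Za-z]", lines[1])) lines <- lines[-1]
  if (!length(lines)) {
    warning("empty Arduino log", call. = FALSE)
    out <- data.frame(time_s = numeric(), perch_g = numeric(),
                      food_g = numeric(), water_g = numeric())
    attr(out, "tare_times") <- tare_times
    attr(out, "n_skipped") <- 0L
    attr(out, "gaps") <- data.frame(after_s = numeric(), gap_s = numeric())
    return(out)
  }
  # whitespace- or comma-delimited
  parts <- strsplit(trimws(lines), "[,\\s]+")
  ok <- lengths(parts) == 4L
  vals <- suppressWarnings(
    matrix(as.numeric(unlist(parts[ok])), ncol = 4, byrow = TRUE))
  good <- stats::complete.cases(vals)
  n_skipped <- sum(!ok) + sum(!good)
  if (n_skipped > 0)
    warning(sprintf("%d unparseable row(s) skipped", n_skipped),
            call. = FALSE)
  if (n_skipped > 0.1 * length(lines))
    stop(">10% of rows unparseable; refusing to continue", call. = FALSE)
  vals <- vals[good, , drop = FALSE]
  out <- data.frame(time_s = vals[, 1], perch_g = vals[, 2],
                    food_g = vals[, 3], water_g = vals[, 4])
  dt <- diff(out$time_s)
  gap <- which(dt > 1)
  attr(out, "tare_times") <- tare_times
  attr(out, "n_skipped") <- n_skipped
  attr(out, "gaps") <- data.frame(after_s = out$time_s[gap],
                                  gap_s = dt[gap])
  out
}

#' Write / read a gas trace CSV
#'
#' Named-column CSV: `time_s,fo2,fco2,wvp_kpa,bp_kpa,flow_ml_min,marker`.
#'
#' @param trace Gas trace data.frame.
#' @param path File path.
#' @return The path (writer, invisibly) or the gas trace (reader).
#' @export
write_gas_trace <- function(trace, path) {
  utils::write.csv(trace, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_gas_trace
#' @export
read_gas_trace <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  out <- utils::read.csv(path)
  need <- c("time_s", "fo2", "fco2", "wvp_kpa", "bp_kpa", "flow_ml_min",
            "marker")
  miss <- setdiff(need, names(out))
  if (length(miss))
    stop("gas trace is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(out) == 0L) warning("empty gas trace", call. = FALSE)
  out
}

#' Write / read an RFID log CSV
#'
#' Columns `time_s,tag,tb_c`. On read, body temperatures outside the
#' plausibility band are flagged (`implausible` column), not dropped.
#'
#' @param reads RFID data.frame (`time_s`, `tag`, `tb_c`).
#' @param path File path.
#' @param plausible_c Plausibility band for body temperature (deg C).
#' @return The path (writer, invisibly) or the flagged reads (reader).
#' @export
write_rfid_log <- function(reads, path) {
  utils::write.csv(reads, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_rfid_log
#' @export
read_rfid_log <- function(path, plausible_c = c(35, 45)) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  out <- utils::read.csv(path, colClasses = c(tag = "character"))
  miss <- setdiff(c("time_s", "tag", "tb_c"), names(out))
  if (length(miss))
    stop("RFID log is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(out) == 0L) warning("empty RFID log", call. = FALSE)
  out$implausible <- out$tb_c < plausible_c[1] | out$tb_c > plausible_c[2]
  out
}

#' Write / read metabolic points or hourly tables
#'
#' Plain named-column CSVs for the pipeline's intermediate products.
#'
#' @param x Data frame.
#' @param path File path.
#' @return The path (writer, invisibly) or the data frame (reader).
#' @export
write_points <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_points
#' @export
read_points <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  utils::read.csv(path)
}

#' Write / read an experiment configuration as YAML
#'
#' Serializes the scalar fields and programs of an [experiment_config()];
#' reading rebuilds the config through the constructors so invariants are
#' re-checked and omitted keys take their defaults. Unknown keys are an
#' error.
#'
#' @param config [experiment_config()].
#' @param path File path.
#' @return The path (writer, invisibly) or an `experiment_config` (reader).
#' @export
write_config_yaml <- function(config, path) {
  x <- list(
    days = config$days, seed = config$seed,
    lights_on_hour = config$lights_on_hour,
    lights_off_hour = config$lights_off_hour,
    chamber = unclass(config$chamber),
    analyzer = list(lag_o2_s = config$analyzer$lag_o2_s,
                    lag_co2_h2o_s = config$analyzer$lag_co2_h2o_s,
                    response_tau_s = config$analyzer$response_tau_s,
                    noise_sd = as.list(config$analyzer$noise_sd),
                    drift_per_h = as.list(config$analyzer$drift_per_h)),
    load_cell = unclass(config$load_cell),
    ambient = config$ambient,
    refill_every_days = config$refill_every_days,
    refill_food_g = config$refill_food_g,
    refill_water_g = config$refill_water_g,
    thresholds = config$thresholds,
    schedule = list(chambers = config$schedule$slots$chamber[
                      config$schedule$slots$chamber != 0L],
                    dwell_s = config$schedule$slots$dwell_s[2],
                    baseline_dwell_s = config$schedule$slots$dwell_s[1]),
    temperature = as.list(config$temperature),
    humidity = as.list(config$humidity),
    birds = lapply(config$birds, unclass))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- yaml::read_yaml(path)
  known <- c("days", "seed", "lights_on_hour", "lights_off_hour", "chamber",
             "analyzer", "load_cell", "ambient", "refill_every_days",
             "refill_food_g", "refill_water_g", "thresholds", "schedule",
             "temperature", "humidity", "birds")
  bad <- setdiff(names(x), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  an <- x$analyzer
  if (!is.null(an)) {
    an$noise_sd <- unlist(an$noise_sd)
    an$drift_per_h <- unlist(an$drift_per_h)
  }
  args <- list(
    days = x$days %||% 10,
    seed = x$seed %||% 1,
    chamber = if (is.null(x$chamber)) chamber_config()
              else do.call(chamber_config, x$chamber),
    analyzer = if (is.null(an)) analyzer_model()
               else do.call(analyzer_model, an),
    load_cell = if (is.null(x$load_cell)) load_cell_model()
                else do.call(load_cell_model, x$load_cell),
    birds = if (is.null(x$birds)) NULL
            else lapply(x$birds, function(b) do.call(bird_params, b)))
  if (!is.null(x$lights_on_hour)) args$lights_on_hour <- x$lights_on_hour
  if (!is.null(x$lights_off_hour)) args$lights_off_hour <- x$lights_off_hour
  if (!is.null(x$ambient)) args$ambient <- x$ambient
  if (!is.null(x$refill_every_days))
    args$refill_every_days <- x$refill_every_days
  if (!is.null(x$refill_food_g)) args$refill_food_g <- x$refill_food_g
  if (!is.null(x$refill_water_g)) args$refill_water_g <- x$refill_water_g
  if (!is.null(x$thresholds)) args$thresholds <- x$thresholds
  if (!is.null(x$schedule)) args$schedule <- do.call(sampling_schedule,
                                                     x$schedule)
  if (!is.null(x$temperature)) args$temperature <-
    as.data.frame(x$temperature)
  if (!is.null(x$humidity)) args$humidity <- as.data.frame(x$humidity)
  do.call(experiment_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
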