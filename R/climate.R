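#' Daily climate series
#'
#' Container for contiguous daily records of mean PAR and mean air
#' temperature, the only climate inputs the model consumes. Day indices are
#' plain integers (day of year or simulation day) with no calendar
#' semantics; they must be strictly consecutive.
#'
#' @param day Integer day indices, strictly consecutive, no gaps.
#' @param par Daily mean photosynthetically active radiation,
#'   umol m^-2 s^-1; non-negative.
#' @param temperature Daily mean air temperature, degC; within -20..60.
#' @return A data frame of class `climate_series`.
#' @export
#' @examples
#' cl <- climate_series(1:5, par = rep(400, 5), temperature = rep(21, 5))
climate_series <- function(day, par, temperature) {
  df <- data.frame(day = as.integer(day), par = as.numeric(par),
                   temperature = as.numeric(temperature))
  validate_climate(df)
  class(df) <- c("climate_series", "data.frame")
  df
}

#' Validate a climate series
#'
#' Checks day contiguity, PAR non-negativity and the temperature bounds.
#' Errors name the offending day/row.
#'
#' @param df Data frame with columns `day`, `par`, `temperature`.
#' @return The validated data frame, invisibly.
#' @export
validate_climate <- function(df) {
  need <- c("day", "par", "temperature")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("climate series is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) stop("climate series is empty", call. = FALSE)
  if (anyNA(df[need])) stop("climate series contains missing values",
                            call. = FALSE)
  d <- diff(df$day)
  if (any(d != 1L)) {
    i <- which(d != 1L)[1L]
    stop(sprintf(
      "day indices must be strictly consecutive: gap after day %d (row %d), day %d missing",
      df$day[i], i, df$day[i] + 1L), call. = FALSE)
  }
  if (any(df$par < 0)) {
    i <- which(df$par < 0)[1L]
    stop(sprintf("negative PAR (%g) at day %d (row %d)",
                 df$par[i], df$day[i], i), call. = FALSE)
  }
  bad_t <- df$temperature < -20 | df$temperature > 60
  if (any(bad_t)) {
    i <- which(bad_t)[1L]
    stop(sprintf("temperature %g degC at day %d (row %d) outside [-20, 60]",
                 df$temperature[i], df$day[i], i), call. = FALSE)
  }
  invisible(df)
}

#' Read / write a climate series as CSV
#'
#' CSV with header `day,par,temperature`. Lines starting with `#` are
#' treated as metadata comments (e.g. declaring whether `day` is a day of
#' year or a simulation step) and are skipped on read. The round trip is
#' lossless to the written precision.
#'
#' @param path File path.
#' @return [read_climate_csv()]: a [climate_series()].
#' @export
read_climate_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  validate_climate(df)
  climate_series(df$day, df$par, df$temperature)
}

#' @rdname read_climate_csv
#' @param series A [climate_series()].
#' @param comment Optional metadata comment line(s) written with a `#`
#'   prefix before the header.
#' @export
write_climate_csv <- function(series, path, comment = NULL) {
  validate_climate(series)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.csv(as.data.frame(series)[c("day", "par", "temperature")],
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Signal window definition
#'
#' The rank-specific environmental signal of an internode is the mean of a
#' climate variable over a short window anchored before the internode's
#' appearance: by default 4 days starting 6 days before the event, i.e. the
#' inclusive integer days \[event-6, event-3\].
#'
#' @param offset_before_event Days before the event at which the window
#'   starts (default 6).
#' @param width Window width in days (default 4; at least 1).
#' @return A list of class `signal_window`.
#' @export
signal_window <- function(offset_before_event = 6, width = 4) {
  stopifnot(width >= 1, offset_before_event >= 0)
  structure(list(offset_before_event = as.integer(offset_before_event),
                 width = as.integer(width)),
            class = "signal_window")
}

#' Windowed mean of a climate variable (PAR4d / T4d)
#'
#' Arithmetic mean of `par` or `temperature` over the signal window
#' anchored at `event_day`. Window days falling before the series start are
#' dropped and the mean is taken over the remaining days (early internodes'
#' windows predate the series, because the simulation starts with the first
#' internode already present); if no window day exists in the series, the
#' value at the first series day is returned. Truncation is reported via
#' `message()` unless `quiet = TRUE`.
#'
#' @param series A [climate_series()].
#' @param variable `"par"` or `"temperature"`.
#' @param event_day Day index of the anchoring event (internode
#'   appearance); must not lie after the series end.
#' @param window A [signal_window()].
#' @param quiet Suppress the truncation message.
#' @return Mean value in the units of `variable`.
#' @export
#' @examples
#' cl <- climate_series(1:7, par = 1:7 * 100, temperature = rep(20, 7))
#' window_mean(cl, "par", event_day = 7)  # mean of days 1..4 = 250
window_mean <- function(series, variable = c("par", "temperature"),
                        event_day, window = signal_window(),
                        quiet = FALSE) {
  variable <- match.arg(variable)
  stopifnot(nrow(series) > 0)
  if (event_day > max(series$day)) {
    stop(sprintf("event_day %d is after the series end (day %d)",
                 event_day, max(series$day)), call. = FALSE)
  }
  start <- event_day - window$offset_before_event
  days <- seq.int(start, start + window$width - 1L)
  keep <- days[days %in% series$day]
  if (length(keep) == 0L) {
    if (!quiet) message(sprintf(
      "window [%d, %d] for event day %d lies entirely before the series; using first-day value",
      min(days), max(days), event_day))
    return(series[[variable]][1L])
  }
  if (length(keep) < length(days) && !quiet) {
    message(sprintf(
      "window [%d, %d] for event day %d truncated to %d day(s)",
      min(days), max(days), event_day, length(keep)))
  }
  mean(series[[variable]][match(keep, series$day)])
}
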