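# Plain-CSV readers and writers for the three input dialects: hourly body
# temperatures, thermograph profiles, and radio-tracking fixes.

#' Read hourly body-temperature series
#'
#' Expects columns `fish_id`, `timestamp` (ISO-8601), `temp_c` (empty cell
#' = missing).  All fish are aligned to one common hourly grid spanning
#' the full range of timestamps in the file.
#'
#' @param path CSV path.
#' @param tz timezone for timestamp parsing (default UTC).
#' @return List of `"body_temp_series"` objects plus the grid as
#'   attributes `start` and `n_hours`.
#' @export
read_body_temps <- function(path, tz = "UTC") {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("fish_id", "timestamp", "temp_c") %in% names(d)))
  ts <- parse_time(d$timestamp, tz)
  t0 <- min(ts)
  hour <- as.integer(round(difftime(ts, t0, units = "hours"))) + 1L
  n_hours <- max(hour)
  out <- lapply(split(seq_len(nrow(d)), d$fish_id), function(i) {
    temps <- rep(NA_real_, n_hours)
    temps[hour[i]] <- d$temp_c[i]
    structure(list(fish_id = d$fish_id[i[1L]], temps = temps,
                   tactic = NA_character_,
                   missing_fraction = mean(is.na(temps))),
              class = "body_temp_series")
  })
  attr(out, "start") <- t0
  attr(out, "n_hours") <- n_hours
  out
}

#' Write body-temperature series to CSV
#'
#' @param series list of `"body_temp_series"`.
#' @param path output CSV path.
#' @param start timestamp of hour 1.
#' @export
write_body_temps <- function(series, path, start = "2010-07-05") {
  t0 <- as.POSIXct(start, tz = "UTC")
  rows <- lapply(series, function(s) {
    data.frame(fish_id = s$fish_id,
               timestamp = format(t0 + 3600 * (seq_along(s$temps) - 1L),
                                  "%Y-%m-%dT%H:%M:%SZ"),
               temp_c = s$temps)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
}

#' Read a thermograph table into a thermal profile
#'
#' Expects columns `depth_m`, `timestamp`, `temp_c`.
#'
#' @param path CSV path.
#' @param tz timezone.
#' @return A [`thermal_profile`][thermal_profile].
#' @export
read_thermograph <- function(path, tz = "UTC") {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("depth_m", "timestamp", "temp_c") %in% names(d)))
  depths <- sort(unique(d$depth_m))
  ts <- sort(unique(parse_time(d$timestamp, tz)))
  M <- matrix(NA_real_, length(depths), length(ts))
  M[cbind(match(d$depth_m, depths),
          match(parse_time(d$timestamp, tz), ts))] <- d$temp_c
  thermal_profile(depths, M, ts)
}

#' Write a thermal profile as a thermograph CSV
#'
#' @param profile a [`thermal_profile`][thermal_profile].
#' @param path output path.
#' @export
write_thermograph <- function(profile, path) {
  d <- expand.grid(depth_m = profile$depths,
                   timestamp = format(profile$timestamps,
                                      "%Y-%m-%dT%H:%M:%SZ"))
  d$temp_c <- as.vector(profile$temps)
  utils::write.csv(d, path, row.names = FALSE, na = "")
}

#' Read a radio-tracking fix table
#'
#' Expects columns `fish_id`, `timestamp`, `period`, `easting`,
#' `northing`.
#'
#' @param path CSV path.
#' @param tz timezone.
#' @return Data frame of fixes.
#' @export
read_telemetry <- function(path, tz = "UTC") {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("fish_id", "timestamp", "period", "easting", "northing")
                %in% names(d)))
  d$timestamp <- parse_time(d$timestamp, tz)
  bad <- setdiff(unique(d$period), c("dawn", "day", "dusk", "night"))
  if (length(bad))
    stop("unknown period label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  d
}

#' Read an excursion-record CSV
#'
#' @param path CSV with the columns produced by [excursion_frequency()] or
#'   [simulate_excursion_dataset()].
#' @return Data frame of excursion records.
#' @export
read_excursions <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("fish_id", "excursion_pct", "epi_mean", "meta_mean",
            "day_of_year", "year")
  stopifnot(all(need %in% names(d)))
  if ("date" %in% names(d)) d$date <- as.Date(d$date)
  d
}
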