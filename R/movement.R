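# Vertical (epilimnion excursion) and horizontal (travelled distance)
# movement summaries derived from radio-tracking fixes.

#' Daily excursion frequencies into the epilimnion
#'
#' The frequency of daily excursions is the number of fixes at which a
#' fish was in the epilimnion relative to the total number of fixes with
#' defined occupancy for that fish-day, in percent.  Each fish-day is
#' joined with that day's layer covariates (mean epilimnion and
#' metalimnion temperature, day of year, year).
#'
#' @param fixes data frame with `fish_id`, `timestamp` (POSIXct or
#'   coercible), and `epilimnetic` (logical; `NA` = occupancy undefined,
#'   e.g. an unstratified hour).
#' @param layers daily layer table as returned by [daily_layer_means()]
#'   (columns `date`, `epi_mean`, `meta_mean`).
#' @return Data frame of excursion records: `fish_id`, `date`,
#'   `excursion_pct`, `n_fixes`, `epi_mean`, `meta_mean`, `day_of_year`,
#'   `year`.  Fish-days without any defined fix, or without layer
#'   covariates, are dropped with a warning.
#' @export
excursion_frequency <- function(fixes, layers) {
  stopifnot(all(c("fish_id", "timestamp", "epilimnetic") %in% names(fixes)))
  fixes$date <- as.Date(parse_time(fixes$timestamp))
  key <- interaction(fixes$fish_id, fixes$date, drop = TRUE)
  parts <- split(fixes, key)
  rows <- lapply(parts, function(d) {
    occ <- d$epilimnetic[!is.na(d$epilimnetic)]
    if (length(occ) == 0L) {
      warning(sprintf("fish %s on %s: no fix with defined occupancy; dropped",
                      d$fish_id[1L], format(d$date[1L])), call. = FALSE)
      return(NULL)
    }
    data.frame(fish_id = d$fish_id[1L], date = d$date[1L],
               excursion_pct = 100 * mean(occ), n_fixes = length(occ))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no fish-day with defined occupancy", call. = FALSE)
  i <- match(out$date, layers$date)
  if (anyNA(i)) {
    warning(sum(is.na(i)), " fish-day(s) without layer covariates dropped",
            call. = FALSE)
    out <- out[!is.na(i), , drop = FALSE]
    i <- i[!is.na(i)]
  }
  out$epi_mean <- layers$epi_mean[i]
  out$meta_mean <- layers$meta_mean[i]
  out$day_of_year <- as.integer(format(out$date, "%j"))
  out$year <- as.integer(format(out$date, "%Y"))
  rownames(out) <- NULL
  out
}

#' Distances travelled between consecutive fixes
#'
#' Linear (Euclidean, planar UTM) distance between each pair of
#' consecutive locations of a fish, labelled by the arrival fix's period
#' of day, plus daily totals (steps summed on their arrival date).
#'
#' @param fixes data frame with `fish_id`, `timestamp`, `period`,
#'   `easting`, `northing`.
#' @return List with `steps` (`fish_id`, `timestamp`, `date`, `period`,
#'   `distance`) and `daily` (`fish_id`, `date`, `total_distance`,
#'   `n_steps`).
#' @export
travelled_distances <- function(fixes) {
  stopifnot(all(c("fish_id", "timestamp", "period", "easting", "northing")
                %in% names(fixes)))
  fixes$timestamp <- parse_time(fixes$timestamp)
  parts <- split(fixes, fixes$fish_id)
  steps <- lapply(parts, function(d) {
    if (anyDuplicated(d$timestamp))
      stop("ambiguous order: duplicate timestamps for fish ", d$fish_id[1L],
           call. = FALSE)
    d <- d[order(d$timestamp), , drop = FALSE]
    if (nrow(d) < 2L) return(NULL)
    i <- seq_len(nrow(d) - 1L)
    data.frame(fish_id = d$fish_id[1L],
               timestamp = d$timestamp[i + 1L],
               date = as.Date(d$timestamp[i + 1L]),
               period = d$period[i + 1L],
               distance = sqrt(diff(d$easting)^2 + diff(d$northing)^2))
  })
  steps <- do.call(rbind, steps)
  if (is.null(steps))
    steps <- data.frame(fish_id = character(0), timestamp = as.POSIXct(character(0)),
                        date = as.Date(character(0)), period = character(0),
                        distance = numeric(0))
  rownames(steps) <- NULL
  daily <- if (nrow(steps)) {
    agg <- stats::aggregate(distance ~ fish_id + date, steps,
                            function(v) c(sum(v), length(v)))
    data.frame(fish_id = agg$fish_id, date = agg$date,
               total_distance = agg$distance[, 1L],
               n_steps = as.integer(agg$distance[, 2L]))
  } else {
    data.frame(fish_id = character(0), date = as.Date(character(0)),
               total_distance = numeric(0), n_steps = integer(0))
  }
  list(steps = steps, daily = daily)
}

#' Movement summary by period of day and thermal condition
#'
#' Mean, SD and count of step distances in each (period of day) x
#' (epilimnion condition) cell, where the condition is whether the step
#' day's mean epilimnion temperature is above or below a threshold
#' (typically the root split of a fitted excursion tree).
#'
#' @param steps step table from [travelled_distances()].
#' @param layers daily layer table with `date` and `epi_mean`.
#' @param threshold epilimnion temperature threshold in degC.
#' @param periods period vocabulary defining the row order.
#' @return Data frame (`period`, `condition`, `mean`, `sd`, `n`); empty
#'   cells keep `n = 0` with undefined (`NA`) mean.
#' @export
summarize_movement <- function(steps, layers, threshold = 22.4,
                               periods = c("dawn", "day", "dusk", "night")) {
  epi <- layers$epi_mean[match(steps$date, layers$date)]
  cond <- ifelse(epi > threshold, "above", "below")
  keep <- !is.na(cond)
  steps <- steps[keep, , drop = FALSE]
  cond <- cond[keep]
  grid <- expand.grid(period = periods, condition = c("below", "above"),
                      stringsAsFactors = FALSE)
  cells <- lapply(seq_len(nrow(grid)), function(r) {
    v <- steps$distance[steps$period == grid$period[r] &
                          cond == grid$condition[r]]
    data.frame(period = grid$period[r], condition = grid$condition[r],
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
               n = length(v))
  })
  do.call(rbind, cells)
}
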