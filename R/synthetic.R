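# Synthetic study generator: a summer-stratified lake, fish
# body-temperature series composed of scale-specific sinusoids, telemetry
# fixes and excursion datasets with the correlation structure the
# analysis assumes.  Every generator is reproducible under an explicit
# seed and emits valid inputs for the downstream stages.

#' Simulate a summer-stratified lake thermal profile
#'
#' Temperature follows a logistic (sigmoid) depth profile between a warm
#' surface and a cold hypolimnion,
#' \eqn{T(z,t) = T_{hypo} + (T_{surf}(t) - T_{hypo}) / (1 + e^{(z - z_0)/w})},
#' with the surface temperature driven by a linear seasonal ramp plus a
#' diurnal sinusoid peaking mid-afternoon.  Defaults give an epilimnion in
#' the low twenties (degC) over a metalimnion gradient well above
#' 1 degC/m, the regime of a small temperate oligotrophic lake in July.
#'
#' @param days number of days (hourly sampling; default 19, a ~450 h
#'   window).
#' @param hypo_temp hypolimnion temperature, degC.
#' @param surface_base mean surface temperature, degC.
#' @param seasonal_amplitude total linear surface drift over the window,
#'   degC.
#' @param diurnal_amplitude half-range of the daily surface cycle, degC.
#' @param thermocline_depth inflection depth, m.
#' @param thermocline_width logistic width parameter, m.
#' @param noise_sd thermograph measurement noise, degC.
#' @param start first timestamp (UTC midnight of this date).
#' @param seed integer seed.
#' @return A [`thermal_profile`][thermal_profile] with depths 0 to 10 m at
#'   0.5 m steps.
#' @export
simulate_lake <- function(days = 19L, hypo_temp = 6, surface_base = 23.5,
                          seasonal_amplitude = 1.5, diurnal_amplitude = 0.75,
                          thermocline_depth = 3.2, thermocline_width = 0.55,
                          noise_sd = 0.02, start = "2010-07-05", seed = 1L) {
  days <- check_count(days, "days", 1L)
  if (surface_base <= hypo_temp)
    stop("surface temperature must exceed hypolimnion temperature",
         call. = FALSE)
  if (thermocline_depth <= 0 || thermocline_depth >= 10 ||
      thermocline_width <= 0)
    stop("thermocline parameters out of range", call. = FALSE)
  n_hours <- 24L * days
  t_h <- seq_len(n_hours) - 1L
  depths <- seq(0, 10, by = 0.5)
  surf <- surface_base +
    seasonal_amplitude * (t_h / max(t_h, 1) - 0.5) +
    diurnal_amplitude * sin(2 * pi * ((t_h %% 24) - 10) / 24)
  shape <- 1 / (1 + exp((depths - thermocline_depth) / thermocline_width))
  temps <- outer(shape, surf - hypo_temp) + hypo_temp
  temps <- temps + with_seed(seed,
    matrix(stats::rnorm(length(temps), 0, noise_sd), nrow(temps)))
  ts <- as.POSIXct(start, tz = "UTC") + 3600 * t_h
  thermal_profile(depths, temps, ts)
}

#' Specify a synthetic thermoregulatory tactic
#'
#' Bundles the periodic components of a body-temperature series for one of
#' the four tactics: I = diel (24 h) + crepuscular (12 h) + fine (8 h);
#' II = broad (>200 h) + crepuscular + fine; III = broad only; IV = diel
#' only.  Amplitudes default to a dominant component of 1.5-2 degC with
#' weaker finer components, over an AR(1) noise floor mimicking thermal
#' inertia.
#'
#' @param tactic `"I"`, `"II"`, `"III"` or `"IV"`, or `NULL` to pass
#'   `periods`/`amplitudes` explicitly.
#' @param periods component periods, hours.
#' @param amplitudes component amplitudes, degC (same length).
#' @param baseline mean body temperature, degC.
#' @param ar_coef,ar_sd AR(1) noise coefficient and innovation SD (degC).
#' @param missing_rate fraction of hours missing (receiver dropout),
#'   within the 9-35% envelope typical of field data.
#' @return List of class `"tactic_spec"`.
#' @export
tactic_spec <- function(tactic = NULL, periods = NULL, amplitudes = NULL,
                        baseline = 16, ar_coef = 0.6, ar_sd = 0.3,
                        missing_rate = 0.2) {
  presets <- list(
    I = list(periods = c(24, 12, 8), amplitudes = c(1.5, 0.8, 0.6)),
    II = list(periods = c(300, 12, 8), amplitudes = c(1.5, 0.8, 0.6)),
    III = list(periods = 300, amplitudes = 2),
    IV = list(periods = 24, amplitudes = 2))
  if (!is.null(tactic)) {
    tactic <- match.arg(tactic, names(presets))
    if (is.null(periods)) periods <- presets[[tactic]]$periods
    if (is.null(amplitudes)) amplitudes <- presets[[tactic]]$amplitudes
  }
  if (is.null(periods) || is.null(amplitudes) ||
      length(periods) != length(amplitudes))
    stop("'periods' and 'amplitudes' must be given and of equal length",
         call. = FALSE)
  if (any(amplitudes < 0)) stop("amplitudes must be >= 0", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1)
    stop("'missing_rate' must be in [0, 1)", call. = FALSE)
  structure(list(tactic = if (is.null(tactic)) NA_character_ else tactic,
                 periods = periods, amplitudes = amplitudes,
                 baseline = baseline, ar_coef = ar_coef, ar_sd = ar_sd,
                 missing_rate = missing_rate),
            class = "tactic_spec")
}

#' Simulate one fish's hourly body-temperature series
#'
#' Sum of the tactic's sinusoids with seeded random phases, plus AR(1)
#' noise, with missing-completely-at-random dropout at the requested rate
#' (realised exactly up to rounding).
#'
#' @param spec a [`tactic_spec`][tactic_spec].
#' @param n_hours grid length (default 450).
#' @param seed integer seed.
#' @param fish_id identifier carried through the pipeline.
#' @return List of class `"body_temp_series"`: `fish_id`, `temps` (length
#'   `n_hours`, `NA` at missing hours), `tactic`, `missing_fraction`.
#' @export
simulate_fish_series <- function(spec, n_hours = 450L, seed = 1L,
                                 fish_id = "fish1") {
  stopifnot(inherits(spec, "tactic_spec"))
  n_hours <- check_count(n_hours, "n_hours", 4L)
  t_h <- seq_len(n_hours)
  temps <- with_seed(seed, {
    phases <- stats::runif(length(spec$periods), 0, 2 * pi)
    signal <- rep(spec$baseline, n_hours)
    for (i in seq_along(spec$periods))
      signal <- signal + spec$amplitudes[i] *
        sin(2 * pi * t_h / spec$periods[i] + phases[i])
    if (spec$ar_sd > 0) {
      innov <- stats::rnorm(n_hours, 0, spec$ar_sd)
      signal <- signal +
        as.numeric(stats::filter(innov, spec$ar_coef, method = "recursive"))
    }
    n_miss <- round(spec$missing_rate * n_hours)
    if (n_miss > 0) signal[sample(n_hours, n_miss)] <- NA
    signal
  })
  structure(list(fish_id = fish_id, temps = temps, tactic = spec$tactic,
                 missing_fraction = mean(is.na(temps))),
            class = "body_temp_series")
}

#' Simulate a population of fish with mixed tactics
#'
#' @param n_fish number of individuals (default 16).
#' @param tactics tactic label per fish (recycled; default an equal mix of
#'   the four tactics).
#' @param n_hours grid length.
#' @param missing_range range from which each fish's missing-data rate is
#'   drawn (default the field-typical 9-35%).
#' @param seed integer seed.
#' @return List of [`body_temp_series`][simulate_fish_series].
#' @export
simulate_population <- function(n_fish = 16L,
                                tactics = c("I", "II", "III", "IV"),
                                n_hours = 450L,
                                missing_range = c(0.09, 0.35),
                                seed = 1L) {
  n_fish <- check_count(n_fish, "n_fish", 1L)
  tactics <- rep_len(tactics, n_fish)
  rates <- with_seed(seed,
                     stats::runif(n_fish, missing_range[1L], missing_range[2L]))
  lapply(seq_len(n_fish), function(i) {
    simulate_fish_series(
      tactic_spec(tactics[i], missing_rate = rates[i]),
      n_hours = n_hours,
      seed = seed * 1000L + i,
      fish_id = sprintf("fish%02d", i))
  })
}

#' Simulate radio-tracking fixes with temperature-dependent step lengths
#'
#' Random-walk positions with four fixes per day (dawn, day, dusk, night)
#' and gamma-distributed step lengths whose mean depends on whether the
#' day's mean epilimnion temperature exceeds a threshold, emulating
#' reduced horizontal movement during warm spells.
#'
#' @param n_fish number of fish.
#' @param days number of tracking days.
#' @param step_mean_below,step_mean_above mean step length (m) on days
#'   below / above the threshold.
#' @param threshold epilimnion temperature threshold, degC.
#' @param epi_range daily epilimnion mean temperatures are drawn uniformly
#'   from this range, degC.
#' @param start first date.
#' @param seed integer seed.
#' @return List with `fixes` (telemetry fix table: `fish_id`, `timestamp`,
#'   `period`, `easting`, `northing`) and `daily` (`date`, `epi_mean`).
#' @export
simulate_telemetry <- function(n_fish = 16L, days = 20L,
                               step_mean_below = 150, step_mean_above = 60,
                               threshold = 22.4, epi_range = c(20, 26),
                               start = "2010-07-14", seed = 1L) {
  n_fish <- check_count(n_fish, "n_fish", 1L)
  days <- check_count(days, "days", 1L)
  if (step_mean_below <= 0 || step_mean_above <= 0)
    stop("step means must be positive", call. = FALSE)
  periods <- c("dawn", "day", "dusk", "night")
  hours <- c(5L, 12L, 19L, 23L)
  dates <- as.Date(start) + seq_len(days) - 1L
  with_seed(seed, {
    epi_mean <- stats::runif(days, epi_range[1L], epi_range[2L])
    day_mean <- ifelse(epi_mean > threshold, step_mean_above, step_mean_below)
    fixes <- lapply(seq_len(n_fish), function(f) {
      pos <- c(700000, 5165000) + stats::runif(2, 0, 500)
      rows <- vector("list", days * 4L)
      k <- 0L
      for (d in seq_len(days)) for (p in 1:4) {
        step <- stats::rgamma(1, shape = 4, scale = day_mean[d] / 4)
        ang <- stats::runif(1, 0, 2 * pi)
        pos <- pos + step * c(cos(ang), sin(ang))
        k <- k + 1L
        rows[[k]] <- data.frame(
          fish_id = sprintf("fish%02d", f),
          timestamp = as.POSIXct(dates[d], tz = "UTC") + 3600 * hours[p],
          period = periods[p],
          easting = pos[1L], northing = pos[2L])
      }
      do.call(rbind, rows)
    })
    list(fixes = do.call(rbind, fixes),
         daily = data.frame(date = dates, epi_mean = epi_mean))
  })
}

#' Simulate daily excursion records with a thresholded mean structure
#'
#' Generates fish-day excursion frequencies whose expectation is a step
#' function of the lake covariates: a low plateau when the day's
#' epilimnion mean exceeds `epi_threshold`, and otherwise a higher plateau
#' modulated by the metalimnion mean relative to `meta_threshold` —
#' the two-split structure a regression tree should recover.  Covariates
#' are lake-level (shared by all fish on a day).
#'
#' @param n_fish number of fish (sampling units).
#' @param days number of days.
#' @param cell_means named percentages: `above_epi` (epilimnion warmer than
#'   `epi_threshold`), `below_warm_meta` (cool epilimnion, metalimnion
#'   above `meta_threshold`), `below_cold_meta`.
#' @param epi_threshold,meta_threshold generative thresholds, degC.
#' @param noise_sd SD of the truncated Gaussian noise, percentage points.
#' @param epi_range,meta_range covariate ranges, degC.
#' @param start first date; `year` is derived from it.
#' @param seed integer seed.
#' @return Excursion-record data frame (`fish_id`, `date`, `excursion_pct`,
#'   `epi_mean`, `meta_mean`, `day_of_year`, `year`).
#' @export
simulate_excursion_dataset <- function(n_fish = 16L, days = 47L,
                                       cell_means = c(above_epi = 1,
                                                      below_warm_meta = 40,
                                                      below_cold_meta = 10),
                                       epi_threshold = 22.4,
                                       meta_threshold = 12,
                                       noise_sd = 5,
                                       epi_range = c(20, 26),
                                       meta_range = c(10, 15),
                                       start = "2010-07-14", seed = 1L) {
  n_fish <- check_count(n_fish, "n_fish", 1L)
  days <- check_count(days, "days", 1L)
  if (any(cell_means < 0) || any(cell_means > 100) ||
      !all(c("above_epi", "below_warm_meta", "below_cold_meta") %in%
             names(cell_means)))
    stop("'cell_means' must name above_epi, below_warm_meta, below_cold_meta, in [0, 100]",
         call. = FALSE)
  dates <- as.Date(start) + seq_len(days) - 1L
  with_seed(seed, {
    # covariates drawn per fish-day record: each fish's tracking window
    # samples the lake's thermal trajectory differently, so records carry
    # fish-specific covariate values even on overlapping dates
    out <- expand.grid(fish = seq_len(n_fish), day = seq_len(days))
    nr <- nrow(out)
    epi <- stats::runif(nr, epi_range[1L], epi_range[2L])
    meta <- stats::runif(nr, meta_range[1L], meta_range[2L])
    mu <- ifelse(epi > epi_threshold, cell_means[["above_epi"]],
                 ifelse(meta > meta_threshold, cell_means[["below_warm_meta"]],
                        cell_means[["below_cold_meta"]]))
    pct <- pmin(100, pmax(0, mu + stats::rnorm(nr, 0, noise_sd)))
    data.frame(fish_id = sprintf("fish%02d", out$fish),
               date = dates[out$day],
               excursion_pct = pct,
               epi_mean = epi,
               meta_mean = meta,
               day_of_year = as.integer(format(dates[out$day], "%j")),
               year = as.integer(format(dates[out$day], "%Y")))
  })
}
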