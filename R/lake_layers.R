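# Thermal-layer detection in a stratified lake: the metalimnion is the
# portion of the water column with a vertical temperature gradient
# steeper than 1 degC per metre; the epilimnion is the mixed layer above it.

#' Build a thermal profile object
#'
#' @param depths strictly increasing depths in metres (positive downward).
#' @param temps matrix of temperatures, `length(depths)` rows x one column
#'   per hour (`NA` allowed).
#' @param timestamps POSIXct vector, one per column, hourly.
#' @return List of class `"thermal_profile"`.
#' @export
thermal_profile <- function(depths, temps, timestamps) {
  temps <- as.matrix(temps)
  if (any(diff(depths) <= 0))
    stop("'depths' must be strictly increasing", call. = FALSE)
  if (nrow(temps) != length(depths) || ncol(temps) != length(timestamps))
    stop("'temps' must be depths x hours", call. = FALSE)
  structure(list(depths = as.numeric(depths), temps = temps,
                 timestamps = as.POSIXct(timestamps)),
            class = "thermal_profile")
}

#' Detect epilimnion/metalimnion bounds in one hourly profile
#'
#' Computes the downward gradient over each depth interval (converted to
#' degC per metre) and defines the metalimnion as the shallowest maximal
#' contiguous run of intervals with gradient > `threshold`.  The
#' epilimnion spans the depths above the metalimnion top.  With no such
#' run the column is unstratified.
#'
#' @param depths increasing depths (m); only depths with observed
#'   temperature are used (>= 3 required).
#' @param temps temperatures at `depths` (degC), `NA` allowed.
#' @param threshold gradient defining the metalimnion (default 1 degC/m).
#' @return List of class `"layer_bounds"`: `stratified`, `meta_top`,
#'   `meta_bottom` (m; `NA` when unstratified).
#' @examples
#' detect_layers(seq(0, 4, 0.5),
#'               c(25, 24.8, 24.5, 23, 21, 18, 15.5, 14.8, 14.5))
#' @export
detect_layers <- function(depths, temps, threshold = 1) {
  ok <- !is.na(temps)
  if (!any(ok))
    stop("missing profile: no observed temperatures in this column",
         call. = FALSE)
  z <- depths[ok]
  tt <- temps[ok]
  if (length(z) < 3L)
    stop("need at least 3 observed depths", call. = FALSE)
  g <- (tt[-length(tt)] - tt[-1L]) / diff(z)     # degC per metre, downward
  steep <- g > threshold
  if (!any(steep))
    return(structure(list(stratified = FALSE, meta_top = NA_real_,
                          meta_bottom = NA_real_), class = "layer_bounds"))
  r <- rle(steep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  first_run <- which(r$values)[1L]               # shallowest run
  structure(list(stratified = TRUE,
                 meta_top = z[starts[first_run]],
                 meta_bottom = z[ends[first_run] + 1L]),
            class = "layer_bounds")
}

#' Daily layer bounds and mean temperatures
#'
#' For every calendar day, detects the layer bounds in each hourly column
#' and averages temperatures over all (depth, hour) cells falling in each
#' layer.  A depth belongs to the epilimnion when it is above that hour's
#' metalimnion top and to the metalimnion when it lies in
#' `[meta_top, meta_bottom]`; the boundary sensor at `meta_top` is counted
#' with the metalimnion (the layers never overlap).  Daily bounds are the
#' medians over stratified hours.  Days with no stratified hour are
#' omitted with a warning.
#'
#' @param profile a [`thermal_profile`][thermal_profile].
#' @param threshold gradient threshold passed to [detect_layers()].
#' @return Data frame (`date`, `epi_mean`, `meta_mean`, `meta_top`,
#'   `meta_bottom`, `n_hours`).
#' @export
daily_layer_means <- function(profile, threshold = 1) {
  stopifnot(inherits(profile, "thermal_profile"))
  day <- as.Date(profile$timestamps)
  out <- lapply(unique(day), function(d) {
    cols <- which(day == d)
    tops <- numeric(0); bots <- numeric(0)
    epi_cells <- numeric(0); meta_cells <- numeric(0)
    for (j in cols) {
      col <- profile$temps[, j]
      if (all(is.na(col)) || sum(!is.na(col)) < 3L) next
      b <- detect_layers(profile$depths, col, threshold)
      if (!b$stratified) next
      tops <- c(tops, b$meta_top); bots <- c(bots, b$meta_bottom)
      epi_cells <- c(epi_cells, col[profile$depths < b$meta_top])
      meta_cells <- c(meta_cells,
                      col[profile$depths >= b$meta_top &
                          profile$depths <= b$meta_bottom])
    }
    if (length(tops) == 0L) {
      warning("day ", format(d), " has no stratified hour; omitted",
              call. = FALSE)
      return(NULL)
    }
    data.frame(date = d,
               epi_mean = mean(epi_cells, na.rm = TRUE),
               meta_mean = mean(meta_cells, na.rm = TRUE),
               meta_top = stats::median(tops),
               meta_bottom = stats::median(bots),
               n_hours = length(tops))
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    stop("no stratified day in the profile", call. = FALSE)
  res
}

#' Was a fish in the epilimnion at this hour?
#'
#' Occupancy is inferred from temperature: thermo-sensitive transmitters
#' report body temperature, not depth, so a fix counts as epilimnetic when
#' the body temperature reaches the coolest epilimnetic temperature of
#' that hour minus a tolerance absorbing transmitter equilibration lag.
#'
#' @param body_temp fish body temperature (degC).
#' @param depths,temps the hourly profile column (as in [detect_layers()]).
#' @param tolerance matching tolerance in degC (default 0.5).
#' @param threshold gradient threshold for layer detection.
#' @return `TRUE`/`FALSE`; errors when the hour is unstratified (occupancy
#'   undefined).
#' @export
classify_fix_epilimnion <- function(body_temp, depths, temps,
                                    tolerance = 0.5, threshold = 1) {
  b <- detect_layers(depths, temps, threshold)
  if (!b$stratified)
    stop("occupancy undefined: water column not stratified this hour",
         call. = FALSE)
  epi <- temps[depths < b$meta_top]
  if (all(is.na(epi)) || length(epi) == 0L)
    stop("occupancy undefined: no epilimnetic depths this hour", call. = FALSE)
  body_temp >= (min(epi, na.rm = TRUE) - tolerance)
}
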