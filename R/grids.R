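# Grid containers used throughout: daily fields are arrays with dimensions
# [time, lat, lon]; the time axis is a Date vector and lat/lon are cell-centre
# coordinates in degrees (longitude on the 0-360 E convention).

WEATHER_VARS <- c("tmax", "tmin", "rhmax", "rhmin", "wind10", "precip")

#' Construct a daily gridded weather object
#'
#' Bundles daily surface fields on a common time x lat x lon lattice and
#' checks the physical invariants the downstream fire-danger calculations
#' rely on: \code{tmax >= tmin}, \code{0 <= rhmin <= rhmax <= 100},
#' non-negative wind and precipitation, strictly monotone axes.
#'
#' @param dates Date vector (strictly increasing, daily).
#' @param lat,lon numeric cell-centre coordinates, strictly monotone
#'   (degrees; longitude in 0-360 E).
#' @param tmax,tmin daily max/min 2 m air temperature (degC).
#' @param rhmax,rhmin daily max/min relative humidity (percent).
#' @param wind10 daily-mean 10 m wind speed (m/s).
#' @param precip daily accumulated precipitation (mm).
#' @return An object of class \code{weather_grid}.
#' @export
weather_grid <- function(dates, lat, lon, tmax, tmin, rhmax, rhmin,
                         wind10, precip) {
  dates <- as.Date(dates)
  stopifnot(length(dates) >= 1, !anyNA(dates))
  if (length(dates) > 1 && any(diff(as.integer(dates)) != 1L))
    stop("'dates' must be consecutive calendar days")
  .check_axis(lat, "lat")
  .check_axis(lon, "lon")
  dims <- c(length(dates), length(lat), length(lon))
  flds <- list(tmax = tmax, tmin = tmin, rhmax = rhmax, rhmin = rhmin,
               wind10 = wind10, precip = precip)
  for (nm in names(flds)) {
    f <- flds[[nm]]
    if (!is.array(f) || !identical(dim(f), as.integer(dims)))
      stop(sprintf("field '%s' must be a [time, lat, lon] array of dim %s",
                   nm, paste(dims, collapse = "x")))
    if (anyNA(f) || any(!is.finite(f)))
      stop(sprintf("field '%s' contains non-finite values", nm))
  }
  if (any(flds$tmax < flds$tmin)) stop("tmax < tmin somewhere")
  if (any(flds$rhmin < 0) || any(flds$rhmax > 100) ||
      any(flds$rhmin > flds$rhmax))
    stop("relative humidity must satisfy 0 <= rhmin <= rhmax <= 100")
  if (any(flds$wind10 < 0)) stop("wind10 must be non-negative")
  if (any(flds$precip < 0)) stop("precip must be non-negative")
  structure(c(list(dates = dates, lat = as.numeric(lat),
                   lon = as.numeric(lon)), flds),
            class = "weather_grid")
}

.check_axis <- function(x, name) {
  if (length(x) < 1 || anyNA(x)) stop(sprintf("invalid '%s' axis", name))
  if (length(x) > 1 && !(all(diff(x) > 0) || all(diff(x) < 0)))
    stop(sprintf("'%s' axis must be strictly monotone", name))
  invisible(TRUE)
}

#' @export
print.weather_grid <- function(x, ...) {
  cat(sprintf("<weather_grid> %d days (%s to %s), %d x %d cells\n",
              length(x$dates), format(x$dates[1]),
              format(x$dates[length(x$dates)]),
              length(x$lat), length(x$lon)))
  cat(sprintf("  lat %.2f..%.2f, lon %.2f..%.2f (deg E)\n",
              min(x$lat), max(x$lat), min(x$lon), max(x$lon)))
  cat("  fields:", paste(WEATHER_VARS, collapse = ", "), "\n")
  invisible(x)
}

#' Construct a boolean day-flag grid
#'
#' Shared container for binary grid-day classifications (RxDays, air
#' stagnation days): a logical [time, lat, lon] array plus axes and a label
#' recording how the flags were defined.
#'
#' @param dates,lat,lon axes as in \code{\link{weather_grid}}.
#' @param flag logical [time, lat, lon] array.
#' @param label character tag (e.g. the RxDay definition variant).
#' @return An object of class \code{day_grid}.
#' @export
day_grid <- function(dates, lat, lon, flag, label = "day_grid") {
  dates <- as.Date(dates)
  .check_axis(lat, "lat"); .check_axis(lon, "lon")
  dims <- c(length(dates), length(lat), length(lon))
  if (!is.logical(flag) || !identical(dim(flag), as.integer(dims)))
    stop("'flag' must be a logical [time, lat, lon] array matching the axes")
  if (anyNA(flag)) stop("'flag' must not contain NA")
  structure(list(dates = dates, lat = as.numeric(lat), lon = as.numeric(lon),
                 flag = flag, label = label),
            class = "day_grid")
}

#' @export
print.day_grid <- function(x, ...) {
  cat(sprintf("<day_grid:%s> %d days, %d x %d cells, %.1f%% flagged\n",
              x$label, length(x$dates), length(x$lat), length(x$lon),
              100 * mean(x$flag)))
  invisible(x)
}

# days-of-year and meteorological season helpers
.doy <- function(dates) as.integer(strftime(dates, "%j"))

#' Meteorological season of calendar dates
#'
#' @param dates Date vector.
#' @return factor with levels DJF, MAM, JJA, SON.
#' @export
season_of <- function(dates) {
  m <- as.integer(format(as.Date(dates), "%m"))
  s <- c("DJF", "DJF", "MAM", "MAM", "MAM", "JJA",
         "JJA", "JJA", "SON", "SON", "SON", "DJF")[m]
  factor(s, levels = c("DJF", "MAM", "JJA", "SON"))
}

# Season label year: December is attached to the DJF of the following year.
.season_year <- function(dates) {
  y <- as.integer(format(as.Date(dates), "%Y"))
  m <- as.integer(format(as.Date(dates), "%m"))
  ifelse(m == 12L, y + 1L, y)
}

# number of calendar days in a season of a given label year
.season_length <- function(season, year) {
  if (season == "annual") return(365L + as.integer(.is_leap(year)))
  switch(season,
         DJF = 90L + as.integer(.is_leap(year)),
         MAM = 92L, JJA = 92L, SON = 91L,
         stop("unknown season: ", season))
}

.is_leap <- function(y) (y %% 4 == 0 & y %% 100 != 0) | (y %% 400 == 0)

# subset a day_grid (or weather_grid fields) along the time axis
.time_subset <- function(g, keep) {
  g$dates <- g$dates[keep]
  for (nm in names(g)) {
    if (is.array(g[[nm]]) && length(dim(g[[nm]])) == 3L)
      g[[nm]] <- g[[nm]][keep, , , drop = FALSE]
  }
  g
}
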