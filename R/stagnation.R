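# Low-level air stagnation (LLS): days with weak near-surface wind and
# negligible precipitation, a proxy for poor smoke ventilation. Two of the
# three classical air-stagnation-index criteria are used -- the
# mid-tropospheric (500 mb) wind criterion is deliberately omitted, keeping
# the index to daily near-surface quantities.

#' Classify low-level air stagnation for one day
#'
#' TRUE iff daily-mean 10 m wind speed is strictly below the wind threshold
#' and daily accumulated precipitation strictly below the precipitation
#' threshold (defaults 3.2 m/s and 1 mm; equality is not stagnant).
#'
#' @param wind10_mean daily-mean 10 m wind speed, m/s (>= 0).
#' @param precip daily accumulated precipitation, mm (>= 0).
#' @param wind_thresh,precip_thresh thresholds (positive).
#' @return logical. Vectorised.
#' @export
classify_lls <- function(wind10_mean, precip, wind_thresh = 3.2,
                         precip_thresh = 1.0) {
  if (any(wind10_mean < 0) || any(precip < 0))
    stop("wind and precipitation must be >= 0")
  if (wind_thresh < 0 || precip_thresh < 0)
    stop("thresholds must be >= 0")
  wind10_mean < wind_thresh & precip < precip_thresh
}

#' Flag low-level stagnation days over a weather grid
#'
#' @param weather a \code{\link{weather_grid}}.
#' @param wind_thresh,precip_thresh see \code{\link{classify_lls}}.
#' @return a \code{\link{day_grid}} of stagnation flags.
#' @export
lls_grid <- function(weather, wind_thresh = 3.2, precip_thresh = 1.0) {
  stopifnot(inherits(weather, "weather_grid"))
  flag <- classify_lls(weather$wind10, weather$precip, wind_thresh,
                       precip_thresh)
  day_grid(weather$dates, weather$lat, weather$lon,
           array(flag, dim(weather$wind10)), label = "lls")
}

#' Seasonal and annual stagnation-day counts
#'
#' Convenience wrapper: classifies stagnation days and tallies them per
#' season-year and calendar year per cell.
#'
#' @param weather a \code{\link{weather_grid}}.
#' @param seasons which aggregations to return.
#' @param wind_thresh,precip_thresh see \code{\link{classify_lls}}.
#' @return named list of \code{\link{seasonal_counts}} results.
#' @export
lls_counts <- function(weather,
                       seasons = c("annual", "DJF", "MAM", "JJA", "SON"),
                       wind_thresh = 3.2, precip_thresh = 1.0) {
  g <- lls_grid(weather, wind_thresh, precip_thresh)
  out <- lapply(seasons, function(s) seasonal_counts(g, s))
  names(out) <- seasons
  out
}
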