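# Aggregation of boolean day grids into seasonal/annual count climatologies,
# regional means, linear trends, running means, epoch differences,
# interannual variability and ensemble agreement.

#' Define a rectangular analysis region
#'
#' @param name region label.
#' @param lat_range,lon_range inclusive bounds in degrees (lon 0-360 E),
#'   min < max.
#' @return object of class \code{region_box}.
#' @export
region_box <- function(name, lat_range, lon_range) {
  stopifnot(length(lat_range) == 2, length(lon_range) == 2,
            lat_range[1] < lat_range[2], lon_range[1] < lon_range[2])
  structure(list(name = name, lat_range = as.numeric(lat_range),
                 lon_range = as.numeric(lon_range)),
            class = "region_box")
}

#' Western-US analysis regions
#'
#' The full western-US domain box and its three sub-regions: the Pacific
#' Southwest (roughly California and Nevada), the Northern Tier (Pacific
#' Northwest and northern Rockies west of the Front Range) and the Four
#' Corners (Arizona, Utah and the southern Rockies).
#'
#' @return named list of \code{\link{region_box}} objects.
#' @export
wus_regions <- function() {
  list(
    WUS = region_box("WUS", c(31.3, 48.9), c(235.3, 256.9)),
    pacific_southwest = region_box("Pacific Southwest", c(32, 42),
                                   c(235.3, 246)),
    northern_tier = region_box("Northern Tier", c(42, 48.9),
                               c(235.3, 256.9)),
    four_corners = region_box("Four Corners", c(31.3, 42.0),
                              c(246.0, 256.0)))
}

#' Seasonal or annual counts of flagged days
#'
#' Tallies TRUE flags per cell for each complete season-year (or calendar
#' year). December belongs to the following year's DJF, so the first DJF of
#' a series (missing its December) is incomplete; incomplete leading and
#' trailing seasons are dropped rather than reported short.
#'
#' @param x a \code{\link{day_grid}}.
#' @param season one of "annual", "DJF", "MAM", "JJA", "SON".
#' @return object of class \code{count_series}: \code{year} (integer
#'   vector), \code{counts} ([year, lat, lon] array), \code{season},
#'   \code{lat}, \code{lon}.
#' @export
seasonal_counts <- function(x, season = c("annual", "DJF", "MAM", "JJA",
                                          "SON")) {
  season <- match.arg(season)
  stopifnot(inherits(x, "day_grid"))
  if (season == "annual") {
    sel <- rep(TRUE, length(x$dates))
    yr <- as.integer(format(x$dates, "%Y"))
  } else {
    sel <- as.character(season_of(x$dates)) == season
    yr <- .season_year(x$dates)
  }
  if (!any(sel)) stop("no days of season ", season, " in range")
  yr_sel <- yr[sel]
  tally <- table(yr_sel)
  expect <- vapply(as.integer(names(tally)),
                   function(y) .season_length(season, y), integer(1))
  keep_years <- as.integer(names(tally))[as.integer(tally) == expect]
  if (!length(keep_years))
    stop("no complete ", season, " period in range")
  n_lat <- length(x$lat); n_lon <- length(x$lon)
  fm <- matrix(x$flag, length(x$dates), n_lat * n_lon)
  counts <- array(0L, c(length(keep_years), n_lat, n_lon))
  for (i in seq_along(keep_years)) {
    rows <- sel & yr == keep_years[i]
    counts[i, , ] <- colSums(fm[rows, , drop = FALSE])
  }
  structure(list(year = keep_years, counts = counts, season = season,
                 lat = x$lat, lon = x$lon),
            class = "count_series")
}

#' @export
print.count_series <- function(x, ...) {
  cat(sprintf("<count_series:%s> years %d-%d, %d x %d cells\n", x$season,
              min(x$year), max(x$year), length(x$lat), length(x$lon)))
  invisible(x)
}

#' Area-weighted regional mean of a count series
#'
#' Averages per-cell counts over the cells whose centres fall inside the
#' region box (optionally restricted by a land mask), weighting by
#' cos(latitude) so that equal-angle cells contribute by their area.
#'
#' @param cs a \code{\link{seasonal_counts}} result.
#' @param region a \code{\link{region_box}}.
#' @param land_mask optional logical [lat, lon] matrix (TRUE = include);
#'   default includes every cell.
#' @param weights "coslat" (default) or "none".
#' @return data.frame with columns \code{year} and \code{value}.
#' @export
regional_mean <- function(cs, region, land_mask = NULL,
                          weights = c("coslat", "none")) {
  weights <- match.arg(weights)
  stopifnot(inherits(cs, "count_series"), inherits(region, "region_box"))
  in_lat <- cs$lat >= region$lat_range[1] & cs$lat <= region$lat_range[2]
  in_lon <- cs$lon >= region$lon_range[1] & cs$lon <= region$lon_range[2]
  if (!any(in_lat) || !any(in_lon))
    stop("region '", region$name, "' does not overlap the grid")
  cellmask <- outer(in_lat, in_lon)
  if (!is.null(land_mask)) {
    stopifnot(identical(dim(land_mask), dim(cellmask)))
    cellmask <- cellmask & land_mask
    if (!any(cellmask)) stop("no land cells inside region '", region$name, "'")
  }
  w <- if (weights == "coslat")
    outer(cos(cs$lat * pi / 180), rep(1, length(cs$lon))) else
      matrix(1, length(cs$lat), length(cs$lon))
  w[!cellmask] <- 0
  w <- w / sum(w)
  val <- vapply(seq_along(cs$year),
                function(i) sum(cs$counts[i, , ] * w), numeric(1))
  data.frame(year = cs$year, value = val)
}

#' Ordinary least-squares trend of a yearly series
#'
#' Fits value ~ year by OLS and summarises the fit the way burn-window
#' climatologies are reported: the slope (days/year per year), the
#' accumulated change over the fitted period (slope times the year span),
#' the percent change relative to a baseline, and the two-tailed p-value of
#' the slope's t-test.
#'
#' @param values yearly values (or a data.frame with columns year, value).
#' @param years integer years (ignored if \code{values} is a data.frame).
#' @param baseline "fit_start" (fitted value at the first year, the
#'   default) or "mean" (period mean) as the denominator of the percent
#'   change.
#' @return object of class \code{trend_result}: slope, accumulated,
#'   percent, p_value, n_years.
#' @export
linear_trend <- function(values, years = NULL,
                         baseline = c("fit_start", "mean")) {
  baseline <- match.arg(baseline)
  if (is.data.frame(values)) {
    years <- values$year
    values <- values$value
  }
  if (is.null(years)) years <- seq_along(values)
  stopifnot(length(values) == length(years))
  if (length(values) < 3) stop("need at least 3 years for a trend")
  if (length(unique(years)) < 2) stop("constant time axis")
  fit <- lm(values ~ years)
  # perfect fits trigger a harmless "summary may be unreliable" warning
  sm <- suppressWarnings(summary(fit))$coefficients
  slope <- sm["years", "Estimate"]
  p <- sm["years", "Pr(>|t|)"]
  span <- max(years) - min(years)
  accumulated <- slope * span
  base <- switch(baseline,
                 fit_start = unname(coef(fit)[1] + slope * min(years)),
                 mean = mean(values))
  percent <- if (base != 0) 100 * accumulated / base else NA_real_
  structure(list(slope = slope, accumulated = accumulated,
                 percent = percent, p_value = p,
                 n_years = length(values), baseline = base),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf(
    "<trend_result> slope %+.4f/yr, accumulated %+.2f (%+.1f%%), p = %.4g, n = %d\n",
    x$slope, x$accumulated, x$percent, x$p_value, x$n_years))
  invisible(x)
}

#' Centred running mean
#'
#' Centred moving average with truncated (shrinking) windows at the ends so
#' the smoothed series spans the full period.
#'
#' @param x numeric series.
#' @param window odd window length (default 5).
#' @return numeric series of the same length.
#' @export
running_mean <- function(x, window = 5) {
  window <- as.integer(window)
  if (window < 1) stop("window must be >= 1")
  if (length(x) < window) stop("series shorter than window")
  h <- window %/% 2
  n <- length(x)
  vapply(seq_len(n),
         function(i) mean(x[max(1, i - h):min(n, i + h)]), numeric(1))
}

#' Per-cell difference of mean counts between two epochs
#'
#' Mean annual (or seasonal) count over epoch_b minus the mean over
#' epoch_a, per cell.
#'
#' @param cs a \code{\link{seasonal_counts}} result.
#' @param epoch_a,epoch_b integer year vectors (e.g. 1981:2020, 2021:2060).
#' @return [lat, lon] matrix of count differences.
#' @export
epoch_difference <- function(cs, epoch_a, epoch_b) {
  stopifnot(inherits(cs, "count_series"))
  ia <- cs$year %in% epoch_a
  ib <- cs$year %in% epoch_b
  if (!any(ia) || !any(ib)) stop("epoch outside the series range")
  if (length(intersect(intersect(cs$year, epoch_a), epoch_b)))
    warning("epochs overlap")
  ma <- apply(cs$counts[ia, , , drop = FALSE], c(2, 3), mean)
  mb <- apply(cs$counts[ib, , , drop = FALSE], c(2, 3), mean)
  mb - ma
}

#' Interannual standard deviation of counts
#'
#' Sample standard deviation (n-1 denominator) of the per-cell yearly
#' counts.
#'
#' @param cs a \code{\link{seasonal_counts}} result with >= 2 years.
#' @return [lat, lon] matrix.
#' @export
interannual_sd <- function(cs) {
  stopifnot(inherits(cs, "count_series"))
  if (length(cs$year) < 2) stop("need at least 2 years")
  apply(cs$counts, c(2, 3), sd)
}

#' Ensemble mean and trend agreement across members
#'
#' Averages member series year by year and counts how many members' own
#' OLS accumulated changes pass a threshold (e.g. "a decrease of at least
#' 10 days per year over the period").
#'
#' @param member_series list of data.frames (year, value), one per member,
#'   on a common year axis.
#' @param threshold magnitude of accumulated change to test (in the series
#'   units over the full period); NULL skips the agreement count.
#' @param direction "decrease" counts members with accumulated change
#'   <= -threshold; "increase" counts >= +threshold.
#' @return list: \code{mean_series} (data.frame year, value),
#'   \code{accumulated} (per-member numeric), \code{agreement} (integer or
#'   NA), \code{n_members}.
#' @export
ensemble_statistics <- function(member_series, threshold = NULL,
                                direction = c("decrease", "increase")) {
  direction <- match.arg(direction)
  stopifnot(length(member_series) >= 1)
  yrs <- member_series[[1]]$year
  for (m in member_series)
    if (!identical(m$year, yrs)) stop("members have ragged year axes")
  vals <- vapply(member_series, function(m) m$value,
                 numeric(length(yrs)))
  vals <- matrix(vals, nrow = length(yrs))
  mean_series <- data.frame(year = yrs, value = rowMeans(vals))
  accumulated <- vapply(member_series,
                        function(m) linear_trend(m)$accumulated, numeric(1))
  agreement <- if (is.null(threshold)) NA_integer_ else {
    if (direction == "decrease") sum(accumulated <= -abs(threshold))
    else sum(accumulated >= abs(threshold))
  }
  list(mean_series = mean_series, accumulated = accumulated,
       agreement = agreement, n_members = length(member_series))
}
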