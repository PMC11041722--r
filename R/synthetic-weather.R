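# Stochastic daily weather generator. Each field is built as
#   seasonal climatology + latitudinal gradient + secular trend
#   + AR(1) anomalies (spatially smoothed innovations),
# with precipitation as a spatially coherent Bernoulli wet-day process and
# gamma-distributed wet-day amounts. The generator emulates the statistical
# structure of 4-km gridded daily meteorology (gridMET-like observations and
# MACA-like downscaled model members) at desk scale.

# modelled primitive variables; tmin/rhmax are derived from dtr/rh_range so
# that tmax >= tmin and rhmax >= rhmin hold by construction
CLIM_VARS <- c("tmax", "dtr", "rhmin", "rh_range", "wind10")

#' Specification for the synthetic climate generator
#'
#' Defines the grid, period, per-variable seasonal climatology
#' (annual mean + cosine amplitude + phase), linear trends (units per
#' decade), AR(1) anomaly model, wet-day precipitation process, spatial
#' structure and master random seed. Temperatures are parameterised as
#' \code{tmax} plus a diurnal range \code{dtr} (so \code{tmin = tmax - dtr}),
#' and humidity as \code{rhmin} plus \code{rh_range}, which keeps the
#' physical orderings intact for any parameter choice. Defaults emulate a
#' mid-latitude western-US interior climate: warm-season temperature peak,
#' cool-season humidity peak, mostly cool-season precipitation.
#'
#' @param n_lat,n_lon grid size.
#' @param lat_range,lon_range axis bounds in degrees (lon in 0-360 E).
#' @param start,end first/last calendar dates (proleptic Gregorian, leap days
#'   included).
#' @param clim named list over \code{tmax,dtr,rhmin,rh_range,wind10}; each a
#'   numeric vector \code{c(mean=, amp=, peak=)} where \code{peak} is the
#'   day-of-year of the climatological maximum. Units: degC, degC, \%, \%, m/s.
#' @param trend named numeric, units per decade, applied linearly in time
#'   (any subset of the five variables).
#' @param sd named numeric, stationary anomaly standard deviation per
#'   variable.
#' @param ar1 lag-1 autocorrelation of daily anomalies, in [0,1).
#' @param t_rh_cor correlation imposed between tmax and rhmin anomalies
#'   (negative: hot days are dry days).
#' @param lat_gradient named numeric, units per degree latitude (deviation
#'   from the domain-centre climatology).
#' @param wet_prob named numeric, wet-day probability per season
#'   (DJF/MAM/JJA/SON), each in [0,1].
#' @param wet_prob_trend additive change in wet-day probability per decade.
#' @param precip_shape,precip_scale gamma parameters of wet-day amounts (mm).
#' @param spatial_smooth standard deviation (in grid cells) of the Gaussian
#'   kernel smoothing anomaly innovations; 0 disables spatial correlation.
#' @param seed master integer seed; per-variable streams are derived from it.
#' @return An object of class \code{climate_spec}.
#' @export
climate_spec <- function(n_lat = 10, n_lon = 10,
                         lat_range = c(31.3, 48.9),
                         lon_range = c(235.3, 256.9),
                         start = "1981-01-01", end = "1990-12-31",
                         clim = list(
                           tmax     = c(mean = 18, amp = 12, peak = 200),
                           dtr      = c(mean = 13, amp = 2,  peak = 200),
                           rhmin    = c(mean = 30, amp = 14, peak = 20),
                           rh_range = c(mean = 38, amp = 8,  peak = 20),
                           wind10   = c(mean = 3.1, amp = 0.6, peak = 105)),
                         trend = c(tmax = 0),
                         sd = c(tmax = 4, dtr = 1.5, rhmin = 10,
                                rh_range = 6, wind10 = 1.1),
                         ar1 = 0.7, t_rh_cor = -0.6,
                         lat_gradient = c(tmax = -0.55, rhmin = 0.4),
                         wet_prob = c(DJF = 0.35, MAM = 0.25,
                                      JJA = 0.10, SON = 0.20),
                         wet_prob_trend = 0,
                         precip_shape = 0.7, precip_scale = 8,
                         spatial_smooth = 1.5,
                         seed = 1L) {
  start <- as.Date(start); end <- as.Date(end)
  if (is.na(start) || is.na(end) || end < start)
    stop("invalid date range: 'end' must be >= 'start'")
  stopifnot(n_lat >= 1, n_lon >= 1,
            lat_range[1] < lat_range[2] || n_lat == 1,
            lon_range[1] < lon_range[2] || n_lon == 1)
  for (v in CLIM_VARS) {
    if (!v %in% names(clim) ||
        !all(c("mean", "amp", "peak") %in% names(clim[[v]])))
      stop("clim$", v, " must provide mean, amp and peak")
  }
  sd <- .fill_named(sd, CLIM_VARS, 0)
  if (any(sd < 0)) stop("anomaly standard deviations must be >= 0")
  trend <- .fill_named(trend, CLIM_VARS, 0)
  lat_gradient <- .fill_named(lat_gradient, CLIM_VARS, 0)
  if (ar1 < 0 || ar1 >= 1) stop("ar1 must be in [0, 1)")
  if (abs(t_rh_cor) > 1) stop("t_rh_cor must be in [-1, 1]")
  wp <- .fill_named(wet_prob, c("DJF", "MAM", "JJA", "SON"), 0)
  if (any(wp < 0 | wp > 1)) stop("wet-day probabilities must be in [0, 1]")
  # RH climatology must stay inside [0, 100] (anomalies are clipped later)
  rh_lo <- clim$rhmin[["mean"]] - abs(clim$rhmin[["amp"]])
  rh_hi <- clim$rhmin[["mean"]] + abs(clim$rhmin[["amp"]]) +
    clim$rh_range[["mean"]] + abs(clim$rh_range[["amp"]])
  if (rh_lo < -1e-9) stop("rhmin climatology dips below 0%")
  stopifnot(precip_shape > 0, precip_scale > 0, spatial_smooth >= 0)
  structure(list(n_lat = n_lat, n_lon = n_lon, lat_range = lat_range,
                 lon_range = lon_range, start = start, end = end,
                 clim = clim, trend = trend, sd = sd, ar1 = ar1,
                 t_rh_cor = t_rh_cor, lat_gradient = lat_gradient,
                 wet_prob = wp, wet_prob_trend = wet_prob_trend,
                 precip_shape = precip_shape, precip_scale = precip_scale,
                 spatial_smooth = spatial_smooth, seed = as.integer(seed)),
            class = "climate_spec")
}

.fill_named <- function(x, nms, default) {
  out <- setNames(rep(default, length(nms)), nms)
  if (length(x)) {
    bad <- setdiff(names(x), nms)
    if (length(bad)) stop("unknown variable(s): ", paste(bad, collapse = ", "))
    out[names(x)] <- x
  }
  out
}

# deterministic per-stream seed derived from the master seed and a key
.derive_seed <- function(master, key) {
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)) * 131L)
  as.integer((as.numeric(master) * 48271 + h) %% 2147483647)
}

# Gaussian smoothing matrix along one axis; rows rescaled so that smoothing
# iid N(0,1) noise leaves the per-position variance at exactly 1.
.smooth_matrix <- function(n, sd_cells) {
  if (sd_cells <= 0 || n == 1) return(diag(n))
  w <- outer(seq_len(n), seq_len(n),
             function(i, j) exp(-(i - j)^2 / (2 * sd_cells^2)))
  w / sqrt(rowSums(w^2))
}

# [T x ncell] matrix of N(0,1) innovations with spatial correlation imposed
# by separable Gaussian smoothing over the lat/lon layout.
.smoothed_noise <- function(nt, n_lat, n_lon, smooth_sd) {
  e <- matrix(rnorm(nt * n_lat * n_lon), nrow = nt)
  if (smooth_sd > 0 && n_lat * n_lon > 1) {
    s_lat <- .smooth_matrix(n_lat, smooth_sd)
    s_lon <- .smooth_matrix(n_lon, smooth_sd)
    a <- array(e, c(nt, n_lat, n_lon))
    for (j in seq_len(n_lon)) a[, , j] <- a[, , j] %*% t(s_lat)
    for (i in seq_len(n_lat)) a[, i, ] <- a[, i, ] %*% t(s_lon)
    e <- matrix(a, nrow = nt)
  }
  e
}

# AR(1) filter columns of a [T x ncell] innovation matrix; innovations scaled
# so the stationary variance is 1.
.ar1_filter <- function(e, rho) {
  if (rho == 0) return(e)
  out <- stats::filter(e * sqrt(1 - rho^2), rho, method = "recursive")
  matrix(as.numeric(out), nrow = nrow(e))
}

#' Generate a synthetic daily gridded weather series
#'
#' Realises the process defined by a \code{\link{climate_spec}}: per-variable
#' seasonal cycles plus latitudinal gradients and linear trends, AR(1)
#' anomalies with spatially smoothed innovations, tmax/rhmin anomalies
#' anti-correlated (hot days are dry days), and a seasonal Bernoulli-gamma
#' precipitation process with spatially coherent wet days. All fields are
#' clipped to physical ranges; output is bit-reproducible given the spec
#' (which carries the seed).
#'
#' @param spec a \code{\link{climate_spec}}.
#' @return A \code{\link{weather_grid}}.
#' @export
generate_weather_grid <- function(spec) {
  stopifnot(inherits(spec, "climate_spec"))
  dates <- seq(spec$start, spec$end, by = "day")
  nt <- length(dates)
  lat <- .axis_points(spec$lat_range, spec$n_lat)
  lon <- .axis_points(spec$lon_range, spec$n_lon)
  ncell <- spec$n_lat * spec$n_lon
  doy <- .doy(dates)
  yrs <- as.numeric(dates - dates[1]) / 365.25     # years since start
  lat_cell <- rep(lat - mean(lat), times = spec$n_lon)   # [ncell]

  # anomaly fields, per-variable streams; tmax drawn first so rhmin can be
  # anti-correlated with it
  anom <- list()
  for (v in CLIM_VARS) {
    set.seed(.derive_seed(spec$seed, v))
    e <- .smoothed_noise(nt, spec$n_lat, spec$n_lon, spec$spatial_smooth)
    anom[[v]] <- .ar1_filter(e, spec$ar1)
  }
  if (spec$t_rh_cor != 0) {
    r <- spec$t_rh_cor
    anom$rhmin <- r * anom$tmax + sqrt(1 - r^2) * anom$rhmin
  }

  field <- function(v) {
    cl <- spec$clim[[v]]
    season <- cl[["mean"]] +
      cl[["amp"]] * cos(2 * pi * (doy - cl[["peak"]]) / 365.25)
    base <- season + spec$trend[[v]] * yrs / 10                   # [T]
    outer(base, rep(1, ncell)) +
      outer(rep(1, nt), spec$lat_gradient[[v]] * lat_cell) +
      spec$sd[[v]] * anom[[v]]
  }

  tmax <- field("tmax")
  dtr <- pmax(field("dtr"), 0.5)
  rhmin <- pmin(pmax(field("rhmin"), 0), 100)
  rh_range <- pmax(field("rh_range"), 0)
  rhmax <- pmin(rhmin + rh_range, 100)
  wind10 <- pmax(field("wind10"), 0)

  # precipitation: spatially coherent wet-day occurrence via thresholding a
  # smoothed Gaussian field, iid gamma amounts on wet days
  set.seed(.derive_seed(spec$seed, "precip"))
  occ_noise <- .smoothed_noise(nt, spec$n_lat, spec$n_lon, spec$spatial_smooth)
  p_wet <- spec$wet_prob[as.character(season_of(dates))] +
    spec$wet_prob_trend * yrs / 10
  p_wet <- pmin(pmax(p_wet, 0), 1)
  wet <- pnorm(occ_noise) < p_wet                       # recycles over cells
  amt <- matrix(0, nt, ncell)
  nwet <- sum(wet)
  if (nwet > 0)
    amt[wet] <- rgamma(nwet, shape = spec$precip_shape,
                       scale = spec$precip_scale)

  arr <- function(m) array(m, c(nt, spec$n_lat, spec$n_lon))
  weather_grid(dates, lat, lon,
               tmax = arr(tmax), tmin = arr(tmax - dtr),
               rhmax = arr(rhmax), rhmin = arr(rhmin),
               wind10 = arr(wind10), precip = arr(amt))
}

.axis_points <- function(range, n) {
  if (n == 1) return(mean(range))
  seq(range[1], range[2], length.out = n)
}

#' Generate a spatially coherent forest / non-forest mask
#'
#' Stand-in for a vegetation classification raster (forest & woodland vs
#' everything else): a Gaussian random field is smoothed to the requested
#' coherence and thresholded by rank so that the realised forest fraction is
#' exact to within one cell.
#'
#' @param lat,lon grid axes (cell centres).
#' @param forest_fraction target fraction of forest cells, in [0,1].
#' @param seed integer seed.
#' @param smooth_sd Gaussian kernel standard deviation in cells.
#' @return An object of class \code{vegetation_mask}: list with \code{lat},
#'   \code{lon} and logical [lat, lon] matrix \code{forest}.
#' @export
generate_vegetation_mask <- function(lat, lon, forest_fraction, seed = 1L,
                                     smooth_sd = 1.5) {
  if (forest_fraction < 0 || forest_fraction > 1)
    stop("forest_fraction must be in [0, 1]")
  .check_axis(lat, "lat"); .check_axis(lon, "lon")
  n_lat <- length(lat); n_lon <- length(lon)
  set.seed(.derive_seed(seed, "vegmask"))
  fld <- .smoothed_noise(1, n_lat, n_lon, smooth_sd)
  k <- round(forest_fraction * n_lat * n_lon)
  forest <- matrix(rank(fld[1, ], ties.method = "first") <= k, n_lat, n_lon)
  structure(list(lat = as.numeric(lat), lon = as.numeric(lon),
                 forest = forest),
            class = "vegetation_mask")
}

#' @export
print.vegetation_mask <- function(x, ...) {
  cat(sprintf("<vegetation_mask> %d x %d cells, %.1f%% forest\n",
              length(x$lat), length(x$lon), 100 * mean(x$forest)))
  invisible(x)
}

#' Specification of a pseudo-model ensemble
#'
#' Describes a set of ensemble members as perturbations of a base climate
#' process: per-member additive biases on the climatological means and
#' per-member trend perturbations (both named over the generator's primitive
#' variables), plus per-member seeds. With the default seeds, member 1
#' reproduces the base realisation exactly and later members are independent
#' realisations; pass identical seeds to share the realisation across
#' members (isolating the bias structure).
#'
#' @param n_members number of members (>= 1).
#' @param bias list of length \code{n_members}; each element a named numeric
#'   of additive climatology-mean offsets (may be NULL for none).
#' @param trend_perturb list like \code{bias}, additive units-per-decade
#'   trend offsets.
#' @param member_seeds optional integer vector of per-member seeds; default
#'   derives them from the base spec's seed at generation time.
#' @return An object of class \code{ensemble_spec}.
#' @export
ensemble_spec <- function(n_members, bias = NULL, trend_perturb = NULL,
                          member_seeds = NULL) {
  n_members <- as.integer(n_members)
  if (n_members < 1) stop("n_members must be >= 1")
  pad <- function(x) {
    if (is.null(x)) x <- vector("list", n_members)
    if (length(x) != n_members)
      stop("per-member perturbation lists must have length n_members")
    x
  }
  if (!is.null(member_seeds) && length(member_seeds) != n_members)
    stop("member_seeds must have length n_members")
  structure(list(n_members = n_members, bias = pad(bias),
                 trend_perturb = pad(trend_perturb),
                 member_seeds = member_seeds),
            class = "ensemble_spec")
}

#' Generate a pseudo-model ensemble of weather grids
#'
#' Applies each member's additive climatology bias and trend perturbation to
#' the base \code{\link{climate_spec}} and generates one
#' \code{\link{weather_grid}} per member. Because biases enter through the
#' climatology, a member with bias b and the base realisation's seed differs
#' from the base grid by exactly b (before physical clipping).
#'
#' @param spec base \code{\link{climate_spec}}.
#' @param ens an \code{\link{ensemble_spec}}.
#' @return list of \code{\link{weather_grid}} objects, one per member.
#' @export
generate_ensemble <- function(spec, ens) {
  stopifnot(inherits(spec, "climate_spec"), inherits(ens, "ensemble_spec"))
  lapply(seq_len(ens$n_members), function(i) {
    si <- spec
    b <- ens$bias[[i]]
    if (!is.null(b)) {
      b <- .fill_named(b, CLIM_VARS, 0)
      for (v in CLIM_VARS) si$clim[[v]][["mean"]] <-
          si$clim[[v]][["mean"]] + b[[v]]
    }
    tp <- ens$trend_perturb[[i]]
    if (!is.null(tp)) {
      tp <- .fill_named(tp, CLIM_VARS, 0)
      si$trend <- si$trend + tp
    }
    si$seed <- if (!is.null(ens$member_seeds)) as.integer(ens$member_seeds[i])
               else as.integer((spec$seed + 1000003 * (i - 1)) %% 2147483647)
    generate_weather_grid(si)
  })
}
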