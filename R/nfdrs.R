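# NFDRS (1978/1985 formulation) dead fuel moisture and ignition component.
# Public interfaces take SI units (degC, %, mm, m/s); conversion to degF
# happens once at this module's boundary. All empirical constants are frozen
# in nfdrs_constants() for auditability.

#' NFDRS constant table
#'
#' All empirical constants of the 1978/1985 NFDRS dead-fuel-moisture and
#' ignition-component formulation used by this package, in one place.
#'
#' @return named list of constants.
#' @export
nfdrs_constants <- function() {
  list(
    # equilibrium moisture content, three RH regimes (T in degF, RH in %)
    emc_lo = c(0.03229, 0.281073, 0.000578),          # RH < 10
    emc_mid = c(2.22749, 0.160107, 0.01478),          # 10 <= RH <= 50
    emc_hi = c(21.0606, 0.005565, 0.00035, 0.483199), # RH > 50
    fm1_scale = 1.03, fm10_scale = 1.28,
    # 100-h: boundary ((24-PDUR)*EMC + PDUR*(0.5*PDUR + 41))/24,
    # daily update fraction 1 - 0.87 exp(-0.24)
    bnd100_a = 0.5, bnd100_b = 41,
    frac100 = 1 - 0.87 * exp(-0.24),
    # 1000-h: boundary ((24-PDUR)*EMC + PDUR*(2.7*PDUR + 76))/24, averaged
    # over a trailing 7-day window, update fraction 1 - 0.82 exp(-0.168)
    bnd1000_a = 2.7, bnd1000_b = 76,
    frac1000 = 1 - 0.82 * exp(-0.168),
    bnd1000_window = 7L,
    # ignition component: heat of ignition -> chi -> probability of ignition
    qign = c(144.5, 0.266, 0.00058, 0.01, 18.54, 0.151, 6.4),
    chi_div = 10, chi_exp = 3.66, pi_scale = 0.000923 / 50,
    # precipitation duration model (daily amounts -> hours)
    pdur_trace_mm = 0.25, pdur_mm_per_hr = 5, pdur_cap_hr = 8
  )
}

#' Convert Celsius to Fahrenheit
#' @param temp_c temperature in degC.
#' @return temperature in degF.
#' @export
c_to_f <- function(temp_c) temp_c * 9 / 5 + 32

#' Equilibrium moisture content
#'
#' Moisture content (percent of dry weight) that a dead fuel element
#' approaches under constant temperature and humidity; three-regime
#' polynomial in relative humidity and dry-bulb temperature.
#'
#' @param temp_f dry-bulb temperature, degF.
#' @param rh relative humidity, percent (0-100).
#' @return EMC in percent, >= 0. Vectorised.
#' @export
equilibrium_moisture_content <- function(temp_f, rh) {
  if (any(rh < 0 | rh > 100, na.rm = TRUE))
    stop("rh must be within [0, 100]")
  if (any(!is.finite(temp_f))) stop("temp_f must be finite")
  k <- nfdrs_constants()
  lo <- k$emc_lo[1] + k$emc_lo[2] * rh - k$emc_lo[3] * rh * temp_f
  mid <- k$emc_mid[1] + k$emc_mid[2] * rh - k$emc_mid[3] * temp_f
  hi <- k$emc_hi[1] + k$emc_hi[2] * rh^2 - k$emc_hi[3] * rh * temp_f -
    k$emc_hi[4] * rh
  out <- ifelse(rh < 10, lo, ifelse(rh <= 50, mid, hi))
  pmax(out, 0)
}

#' Hours of daylight
#'
#' Day length from standard solar declination geometry; used to weight the
#' daytime and night-time equilibrium moisture contents.
#'
#' @param latitude degrees north; must satisfy |latitude| < 66.5.
#' @param day_of_year integer day of year (1-366).
#' @return hours of daylight, in (0, 24). Vectorised.
#' @export
daylength_hours <- function(latitude, day_of_year) {
  if (any(abs(latitude) >= 66.5))
    stop("polar latitudes (|lat| >= 66.5) not supported")
  decl <- 0.4093 * sin(2 * pi * (284 + day_of_year) / 365)
  cos_ha <- -tan(latitude * pi / 180) * tan(decl)
  cos_ha <- pmin(pmax(cos_ha, -1), 1)
  24 * acos(cos_ha) / pi
}

#' Daylight-weighted mean equilibrium moisture content
#'
#' Weights the daytime EMC (from Tmax, RHmin) and night-time EMC (from Tmin,
#' RHmax) by the hours of daylight:
#' \code{(D * emc_min + (24 - D) * emc_max) / 24}.
#'
#' @param emc_min daytime EMC (percent), evaluated at (Tmax, RHmin).
#' @param emc_max night-time EMC (percent), evaluated at (Tmin, RHmax).
#' @param daylight hours of daylight, in (0, 24].
#' @return weighted EMC, percent.
#' @export
emc_bar <- function(emc_min, emc_max, daylight) {
  if (any(daylight <= 0 | daylight > 24)) stop("daylight must be in (0, 24]")
  (daylight * emc_min + (24 - daylight) * emc_max) / 24
}

#' Precipitation duration from daily amounts
#'
#' Daily data carry precipitation amounts but the 100/1000-h boundary
#' formulas need precipitation duration; this monotone capped model supplies
#' it: 0 h below a trace threshold, otherwise \code{ceiling(mm / 5)} hours
#' capped at 8.
#'
#' @param precip_mm daily precipitation, mm (>= 0).
#' @param trace_mm,mm_per_hr,cap_hr model parameters (see
#'   \code{\link{nfdrs_constants}}).
#' @return integer hours in [0, cap_hr]. Vectorised.
#' @export
precip_duration <- function(precip_mm,
                            trace_mm = nfdrs_constants()$pdur_trace_mm,
                            mm_per_hr = nfdrs_constants()$pdur_mm_per_hr,
                            cap_hr = nfdrs_constants()$pdur_cap_hr) {
  if (any(precip_mm < 0)) stop("precip must be >= 0")
  ifelse(precip_mm < trace_mm, 0,
         pmin(cap_hr, ceiling(precip_mm / mm_per_hr)))
}

#' 1-hour and 10-hour dead fuel moisture
#'
#' Fine dead fuel moisture scaled from the daylight-weighted EMC.
#'
#' @param emc weighted equilibrium moisture content, percent.
#' @return fuel moisture, percent.
#' @export
fm1 <- function(emc) nfdrs_constants()$fm1_scale * emc

#' @rdname fm1
#' @export
fm10 <- function(emc) nfdrs_constants()$fm10_scale * emc

#' Daily boundary conditions for 100-h and 1000-h fuel moisture
#'
#' The moisture value toward which the heavy-fuel classes relax on a given
#' day, mixing the weighted EMC over dry hours with a wet-hours term driven
#' by precipitation duration.
#'
#' @param emc weighted EMC, percent.
#' @param pdur precipitation duration, hours (0-8).
#' @return boundary moisture, percent.
#' @export
fm100_boundary <- function(emc, pdur) {
  k <- nfdrs_constants()
  ((24 - pdur) * emc + pdur * (k$bnd100_a * pdur + k$bnd100_b)) / 24
}

#' @rdname fm100_boundary
#' @export
fm1000_boundary <- function(emc, pdur) {
  k <- nfdrs_constants()
  ((24 - pdur) * emc + pdur * (k$bnd1000_a * pdur + k$bnd1000_b)) / 24
}

#' One relaxation step of the 100-h / 1000-h fuel moisture recursions
#'
#' First-order relaxation of the previous day's moisture toward the day's
#' boundary condition (for 1000-h fuels, the trailing 7-day mean boundary):
#' \code{prev + (boundary - prev) * frac} with the class's fixed update
#' fraction. The retained fraction \code{1 - frac} gives the closed-form
#' geometric approach to a constant boundary.
#'
#' @param prev previous-day fuel moisture, percent.
#' @param boundary today's (100-h) or trailing 7-day mean (1000-h) boundary,
#'   percent.
#' @return updated fuel moisture, percent.
#' @export
fm100_step <- function(prev, boundary) {
  if (any(prev < 0) || any(boundary < 0)) stop("moisture must be >= 0")
  prev + (boundary - prev) * nfdrs_constants()$frac100
}

#' @rdname fm100_step
#' @export
fm1000_step <- function(prev, boundary) {
  if (any(prev < 0) || any(boundary < 0)) stop("moisture must be >= 0")
  prev + (boundary - prev) * nfdrs_constants()$frac1000
}

#' Ignition component
#'
#' 0-100 index reflecting the probability that a firebrand produces a
#' spreading ignition, from fine (1-h) dead fuel moisture and dry-bulb
#' temperature: heat-of-ignition polynomial, then the chi transform and the
#' probability-of-ignition power law, truncated to an integer index. It is
#' nonincreasing in fuel moisture and nondecreasing in temperature; moist
#' fuels (>= ~35%) yield 0.
#'
#' @param fm1 1-h dead fuel moisture, percent (>= 0).
#' @param temp_f dry-bulb temperature, degF.
#' @return integer index in [0, 100]. Vectorised.
#' @export
ignition_component <- function(fm1, temp_f) {
  if (any(fm1 < 0)) stop("fm1 must be >= 0")
  k <- nfdrs_constants()
  q <- k$qign
  qign <- q[1] - q[2] * temp_f - q[3] * temp_f^2 - q[4] * temp_f * fm1 +
    q[5] * (1 - exp(-q[6] * fm1)) + q[7] * fm1
  chi <- pmax((344 - qign) / k$chi_div, 0)
  p_i <- pmin(100 * k$pi_scale * chi^k$chi_exp, 100)
  floor(p_i)
}

#' Compute the NFDRS fuel moisture grid from daily weather
#'
#' Runs the full daily chain per grid cell: EMC at (Tmax, RHmin) and
#' (Tmin, RHmax), daylight weighting by latitude and day of year,
#' precipitation duration, the 1-h/10-h scalings, the 100-h and 1000-h
#' boundary-condition recursions (1000-h uses the trailing 7-day mean
#' boundary), and the ignition component at Tmax. The recursions are
#' initialised at their first boundary values (100-h) and the mean of the
#' first seven daily boundaries (1000-h); the first \code{spinup} days are
#' flagged unusable so the heavy-fuel classes forget the initialisation.
#'
#' @param weather a \code{\link{weather_grid}}.
#' @param spinup number of leading days to flag unusable (default 90).
#' @return An object of class \code{fuel_moisture_grid}: axes plus
#'   [time, lat, lon] arrays \code{emc_min}, \code{emc_max}, \code{emc_bar},
#'   \code{fm1}, \code{fm10}, \code{fm100}, \code{fm1000}, \code{ic}, with
#'   attribute \code{spinup}.
#' @export
compute_fuel_moisture <- function(weather, spinup = 90L) {
  stopifnot(inherits(weather, "weather_grid"))
  nt <- length(weather$dates)
  spinup <- as.integer(spinup)
  if (spinup < 0) stop("spinup must be >= 0")
  if (nt <= spinup)
    stop(sprintf("series length (%d) must exceed spinup (%d)", nt, spinup))
  k <- nfdrs_constants()
  n_lat <- length(weather$lat); n_lon <- length(weather$lon)
  ncell <- n_lat * n_lon
  m <- function(a) matrix(a, nt, ncell)

  tmax_f <- c_to_f(m(weather$tmax))
  tmin_f <- c_to_f(m(weather$tmin))
  e_min <- equilibrium_moisture_content(tmax_f, m(weather$rhmin))
  e_max <- equilibrium_moisture_content(tmin_f, m(weather$rhmax))
  doy <- .doy(weather$dates)
  dl_lat <- vapply(weather$lat, function(la) daylength_hours(la, doy),
                   numeric(nt))                     # [T, n_lat]
  dl <- dl_lat[, rep(seq_len(n_lat), times = n_lon), drop = FALSE]
  e_bar <- emc_bar(e_min, e_max, dl)

  pdur <- precip_duration(m(weather$precip))
  b100 <- fm100_boundary(e_bar, pdur)
  b1000 <- fm1000_boundary(e_bar, pdur)

  # trailing 7-day mean of the 1000-h boundary, with shrinking windows at
  # the start; explicit oldest-to-newest adds so the arithmetic matches a
  # scalar per-cell loop bit for bit
  win <- k$bnd1000_window
  b7 <- matrix(0, nt, ncell)
  for (t in seq_len(nt)) {
    i0 <- max(1L, t - win + 1L)
    acc <- b1000[i0, ]
    if (t > i0) for (j in (i0 + 1L):t) acc <- acc + b1000[j, ]
    b7[t, ] <- acc / (t - i0 + 1L)
  }

  fm100 <- matrix(0, nt, ncell)
  fm1000 <- matrix(0, nt, ncell)
  prev100 <- b100[1, ]
  m0 <- min(win, nt)
  acc <- b1000[1, ]
  if (m0 > 1) for (j in 2:m0) acc <- acc + b1000[j, ]
  prev1000 <- acc / m0
  for (t in seq_len(nt)) {
    prev100 <- fm100_step(prev100, b100[t, ])
    fm100[t, ] <- prev100
    prev1000 <- fm1000_step(prev1000, b7[t, ])
    fm1000[t, ] <- prev1000
  }

  arr <- function(x) array(x, c(nt, n_lat, n_lon))
  structure(list(dates = weather$dates, lat = weather$lat, lon = weather$lon,
                 emc_min = arr(e_min), emc_max = arr(e_max),
                 emc_bar = arr(e_bar),
                 fm1 = arr(fm1(e_bar)), fm10 = arr(fm10(e_bar)),
                 fm100 = arr(fm100), fm1000 = arr(fm1000),
                 ic = arr(ignition_component(fm1(e_bar), tmax_f)),
                 spinup = spinup),
            class = "fuel_moisture_grid")
}

#' @export
print.fuel_moisture_grid <- function(x, ...) {
  cat(sprintf(
    "<fuel_moisture_grid> %d days, %d x %d cells, spinup %d days\n",
    length(x$dates), length(x$lat), length(x$lon), x$spinup))
  cat("  fields: emc_min, emc_max, emc_bar, fm1, fm10, fm100, fm1000, ic\n")
  invisible(x)
}
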