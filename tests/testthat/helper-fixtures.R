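# Shared fixtures: tiny specs and deterministic toy grids built in code.

tiny_spec <- function(..., seed = 7L) {
  climate_spec(n_lat = 3, n_lon = 3, start = "1984-10-01",
               end = "1986-12-31", seed = seed, ...)
}

# spec whose realisation is the deterministic seasonal climatology
noiseless_spec <- function(..., n_years = 2) {
  climate_spec(n_lat = 2, n_lon = 2, start = "1981-01-01",
               end = sprintf("%d-12-31", 1980 + n_years),
               sd = c(tmax = 0, dtr = 0, rhmin = 0, rh_range = 0,
                      wind10 = 0),
               wet_prob = c(DJF = 0, MAM = 0, JJA = 0, SON = 0),
               lat_gradient = c(tmax = 0, rhmin = 0),
               seed = 1L, ...)
}

# hand-built constant-weather grid (for fixed-point checks)
constant_weather <- function(n_days = 200, tmax = 25, tmin = 10,
                             rhmax = 70, rhmin = 30, wind10 = 2,
                             precip = 0, n_lat = 2, n_lon = 2) {
  dims <- c(n_days, n_lat, n_lon)
  weather_grid(seq(as.Date("2001-01-01"), by = "day", length.out = n_days),
               lat = seq(35, 40, length.out = n_lat),
               lon = seq(240, 245, length.out = n_lon),
               tmax = array(tmax, dims), tmin = array(tmin, dims),
               rhmax = array(rhmax, dims), rhmin = array(rhmin, dims),
               wind10 = array(wind10, dims), precip = array(precip, dims))
}

# independent scalar per-cell oracle for the fuel moisture recursions;
# mirrors the daily chain with plain scalar arithmetic (explicit
# oldest-to-newest adds for the trailing window)
fm_cell_oracle <- function(weather, i_lat, i_lon) {
  k <- nfdrs_constants()
  nt <- length(weather$dates)
  doy <- as.integer(strftime(weather$dates, "%j"))
  out <- list(fm100 = numeric(nt), fm1000 = numeric(nt))
  b100 <- numeric(nt); b1000 <- numeric(nt)
  for (t in seq_len(nt)) {
    tmax_f <- weather$tmax[t, i_lat, i_lon] * 9 / 5 + 32
    tmin_f <- weather$tmin[t, i_lat, i_lon] * 9 / 5 + 32
    e_min <- equilibrium_moisture_content(tmax_f,
                                          weather$rhmin[t, i_lat, i_lon])
    e_max <- equilibrium_moisture_content(tmin_f,
                                          weather$rhmax[t, i_lat, i_lon])
    dl <- daylength_hours(weather$lat[i_lat], doy[t])
    eb <- (dl * e_min + (24 - dl) * e_max) / 24
    pd <- precip_duration(weather$precip[t, i_lat, i_lon])
    b100[t] <- ((24 - pd) * eb + pd * (0.5 * pd + 41)) / 24
    b1000[t] <- ((24 - pd) * eb + pd * (2.7 * pd + 76)) / 24
  }
  m0 <- min(7L, nt)
  acc <- b1000[1]
  if (m0 > 1) for (j in 2:m0) acc <- acc + b1000[j]
  prev1000 <- acc / m0
  prev100 <- b100[1]
  for (t in seq_len(nt)) {
    prev100 <- prev100 + (b100[t] - prev100) * k$frac100
    out$fm100[t] <- prev100
    i0 <- max(1L, t - 6L)
    acc <- b1000[i0]
    if (t > i0) for (j in (i0 + 1L):t) acc <- acc + b1000[j]
    b7 <- acc / (t - i0 + 1L)
    prev1000 <- prev1000 + (b7 - prev1000) * k$frac1000
    out$fm1000[t] <- prev1000
  }
  out
}

sample_plans <- function(seed = 3L) generate_burn_plans(14, 8, seed = seed)

random_eval_vector <- function() {
  c(temp = runif(1, -10, 45), rh = runif(1, 0, 100),
    midflame_wind = runif(1, 0, 8), fm1 = runif(1, 0, 35),
    fm10 = runif(1, 0, 35), fm100 = runif(1, 0, 35),
    fm1000 = runif(1, 0, 40), ignition_component = runif(1, 0, 100))
}
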