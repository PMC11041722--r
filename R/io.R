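# CF-convention NetCDF readers/writers and burn-plan JSON serialisation.
# Files use dimensions (lon, lat, time) with time as "days since 1900-01-01"
# on the standard (proleptic Gregorian) calendar; units attributes follow CF
# (degC, %, m s-1, mm). Kelvin temperature inputs and -180..180 longitudes
# are normalised on read.

NC_UNITS <- c(tmax = "degC", tmin = "degC", rhmax = "%", rhmin = "%",
              wind10 = "m s-1", precip = "mm")

.nc_time_dim <- function(dates) {
  ncdf4::ncdim_def("time", "days since 1900-01-01",
                   as.numeric(as.Date(dates) - as.Date("1900-01-01")),
                   unlim = TRUE, calendar = "standard")
}

# [time, lat, lon] (internal) <-> [lon, lat, time] (file) layout
.to_file_order <- function(a) aperm(a, c(3, 2, 1))
.from_file_order <- function(a, nt, n_lat, n_lon) {
  a <- array(a, c(n_lon, n_lat, nt))
  aperm(a, c(3, 2, 1))
}

#' Write a weather grid to CF NetCDF
#'
#' @param weather a \code{\link{weather_grid}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_weather_netcdf <- function(weather, path) {
  stopifnot(inherits(weather, "weather_grid"))
  dlon <- ncdf4::ncdim_def("lon", "degrees_east", weather$lon)
  dlat <- ncdf4::ncdim_def("lat", "degrees_north", weather$lat)
  dtim <- .nc_time_dim(weather$dates)
  vars <- lapply(names(NC_UNITS), function(v)
    ncdf4::ncvar_def(v, NC_UNITS[[v]], list(dlon, dlat, dtim),
                     prec = "float"))
  nc <- ncdf4::nc_create(path, vars)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  for (i in seq_along(vars))
    ncdf4::ncvar_put(nc, vars[[i]],
                     .to_file_order(weather[[names(NC_UNITS)[i]]]))
  invisible(path)
}

#' Read a weather grid from CF NetCDF
#'
#' Expects variables tmax, tmin, rhmax, rhmin, wind10, precip on
#' (lon, lat, time). Temperatures with Kelvin units attributes are
#' converted to degC; longitudes on -180..180 are shifted to 0..360.
#'
#' @param path NetCDF file path.
#' @return a \code{\link{weather_grid}}.
#' @export
read_weather_netcdf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  missing <- setdiff(names(NC_UNITS), names(nc$var))
  if (length(missing))
    stop("file lacks required variable(s): ", paste(missing, collapse = ", "))
  lon <- as.numeric(ncdf4::ncvar_get(nc, "lon"))
  lat <- as.numeric(ncdf4::ncvar_get(nc, "lat"))
  lon <- ifelse(lon < 0, lon + 360, lon)
  tdim <- nc$dim$time
  if (is.null(tdim)) stop("file lacks a time dimension")
  origin <- sub("days since\\s+", "", tdim$units)
  dates <- as.Date(substr(origin, 1, 10)) + as.numeric(tdim$vals)
  nt <- length(dates); n_lat <- length(lat); n_lon <- length(lon)
  get <- function(v) {
    x <- .from_file_order(ncdf4::ncvar_get(nc, v, collapse_degen = FALSE),
                          nt, n_lat, n_lon)
    u <- ncdf4::ncatt_get(nc, v, "units")$value
    if (v %in% c("tmax", "tmin") && u %in% c("K", "kelvin", "Kelvin"))
      x <- x - 273.15
    x
  }
  flds <- lapply(names(NC_UNITS), get)
  names(flds) <- names(NC_UNITS)
  do.call(weather_grid, c(list(dates = dates, lat = lat, lon = lon), flds))
}

FM_NC_FIELDS <- c("emc_bar", "fm1", "fm10", "fm100", "fm1000", "ic")

#' Write / read a fuel moisture grid as CF NetCDF
#'
#' Serialises the fields used downstream (emc_bar, fm1, fm10, fm100,
#' fm1000, ic) plus a \code{spinup} global attribute.
#'
#' @param fm a \code{fuel_moisture_grid}.
#' @param path file path.
#' @return \code{path} (write) or a \code{fuel_moisture_grid} (read).
#' @export
write_fm_netcdf <- function(fm, path) {
  stopifnot(inherits(fm, "fuel_moisture_grid"))
  dlon <- ncdf4::ncdim_def("lon", "degrees_east", fm$lon)
  dlat <- ncdf4::ncdim_def("lat", "degrees_north", fm$lat)
  dtim <- .nc_time_dim(fm$dates)
  units <- c(emc_bar = "%", fm1 = "%", fm10 = "%", fm100 = "%",
             fm1000 = "%", ic = "1")
  vars <- lapply(FM_NC_FIELDS, function(v)
    ncdf4::ncvar_def(v, units[[v]], list(dlon, dlat, dtim), prec = "double"))
  nc <- ncdf4::nc_create(path, vars)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  for (i in seq_along(vars))
    ncdf4::ncvar_put(nc, vars[[i]], .to_file_order(fm[[FM_NC_FIELDS[i]]]))
  ncdf4::ncatt_put(nc, 0, "spinup_days", fm$spinup, prec = "int")
  invisible(path)
}

#' @rdname write_fm_netcdf
#' @export
read_fm_netcdf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  lon <- as.numeric(ncdf4::ncvar_get(nc, "lon"))
  lat <- as.numeric(ncdf4::ncvar_get(nc, "lat"))
  tdim <- nc$dim$time
  origin <- sub("days since\\s+", "", tdim$units)
  dates <- as.Date(substr(origin, 1, 10)) + as.numeric(tdim$vals)
  nt <- length(dates); n_lat <- length(lat); n_lon <- length(lon)
  out <- list(dates = dates, lat = lat, lon = lon)
  for (v in FM_NC_FIELDS)
    out[[v]] <- .from_file_order(
      ncdf4::ncvar_get(nc, v, collapse_degen = FALSE), nt, n_lat, n_lon)
  out$spinup <- as.integer(ncdf4::ncatt_get(nc, 0, "spinup_days")$value)
  class(out) <- "fuel_moisture_grid"
  out
}

#' Write / read a boolean day grid as CF NetCDF
#'
#' Flags are stored as byte 0/1 in a variable named \code{flag}, with the
#' grid's label as a global attribute.
#'
#' @param g a \code{\link{day_grid}}.
#' @param path file path.
#' @return \code{path} (write) or a \code{day_grid} (read).
#' @export
write_day_grid_netcdf <- function(g, path) {
  stopifnot(inherits(g, "day_grid"))
  dlon <- ncdf4::ncdim_def("lon", "degrees_east", g$lon)
  dlat <- ncdf4::ncdim_def("lat", "degrees_north", g$lat)
  dtim <- .nc_time_dim(g$dates)
  v <- ncdf4::ncvar_def("flag", "1", list(dlon, dlat, dtim), prec = "byte")
  nc <- ncdf4::nc_create(path, v)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  ncdf4::ncvar_put(nc, v, .to_file_order(array(as.integer(g$flag),
                                               dim(g$flag))))
  ncdf4::ncatt_put(nc, 0, "label", g$label)
  invisible(path)
}

#' @rdname write_day_grid_netcdf
#' @export
read_day_grid_netcdf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  lon <- as.numeric(ncdf4::ncvar_get(nc, "lon"))
  lat <- as.numeric(ncdf4::ncvar_get(nc, "lat"))
  tdim <- nc$dim$time
  origin <- sub("days since\\s+", "", tdim$units)
  dates <- as.Date(substr(origin, 1, 10)) + as.numeric(tdim$vals)
  flag <- .from_file_order(
    ncdf4::ncvar_get(nc, "flag", collapse_degen = FALSE),
    length(dates), length(lat), length(lon))
  label <- ncdf4::ncatt_get(nc, 0, "label")$value
  day_grid(dates, lat, lon, array(flag != 0, dim(flag)),
           label = if (is.character(label)) label else "day_grid")
}

#' Write / read burn plans as JSON
#'
#' Schema per plan: \code{id}, \code{veg_class}, \code{bounds} (variable ->
#' [lower, upper]), \code{units}.
#'
#' @param plans list of \code{\link{burn_plan}} objects.
#' @param path JSON file path.
#' @return \code{path} (write) or a list of plans (read).
#' @export
write_burn_plans <- function(plans, path) {
  units <- c(temp = "degC", rh = "%", midflame_wind = "m s-1", fm1 = "%",
             fm10 = "%", fm100 = "%", fm1000 = "%",
             ignition_component = "index")
  payload <- lapply(plans, function(p) list(
    id = p$id, veg_class = p$veg_class, bounds = p$bounds,
    units = as.list(units[names(p$bounds)])))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_burn_plans
#' @export
read_burn_plans <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(payload, function(p)
    burn_plan(p$id, p$veg_class,
              lapply(p$bounds, function(b) as.numeric(unlist(b)))))
}
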