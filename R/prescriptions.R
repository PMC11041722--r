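# Burn plans, median prescription envelopes and binary RxDay classification.
# A burn plan is a per-variable set of [lower, upper] acceptable ranges; the
# envelope applied to the grid takes, variable by variable, the median of the
# plan lower bounds and the median of the plan upper bounds (forest and
# non-forest plans separately). A grid-day is an RxDay when every bounded
# variable lies inside its envelope (inclusive bounds).

RX_VARS <- c("temp", "rh", "midflame_wind", "fm1", "fm10", "fm100",
             "fm1000", "ignition_component")
HEAVY_FM_VARS <- c("fm100", "fm1000")
FM_VARS <- c("fm1", "fm10", "fm100", "fm1000", "ignition_component")

#' Construct a burn plan
#'
#' @param id plan identifier.
#' @param veg_class "forest" or "non-forest".
#' @param bounds named list over a subset of \code{temp, rh, midflame_wind,
#'   fm1, fm10, fm100, fm1000, ignition_component}; each element
#'   \code{c(lower, upper)} with lower < upper. Units: degC, \%, m/s,
#'   \% dry weight for fuel moistures, index for ignition component.
#'   Non-forest plans must not bound \code{fm100}/\code{fm1000}.
#' @return object of class \code{burn_plan}.
#' @export
burn_plan <- function(id, veg_class = c("forest", "non-forest"), bounds) {
  veg_class <- match.arg(veg_class)
  if (!length(bounds)) stop("a burn plan must bound at least one variable")
  bad <- setdiff(names(bounds), RX_VARS)
  if (length(bad)) stop("unknown variable(s): ", paste(bad, collapse = ", "))
  for (nm in names(bounds)) {
    b <- bounds[[nm]]
    if (length(b) != 2 || anyNA(b) || b[1] >= b[2])
      stop(sprintf("bounds for '%s' must be c(lower, upper) with lower < upper",
                   nm))
    bounds[[nm]] <- as.numeric(b)
  }
  if (veg_class == "non-forest" && any(HEAVY_FM_VARS %in% names(bounds)))
    stop("non-forest plans must not carry fm100/fm1000 bounds")
  structure(list(id = as.character(id), veg_class = veg_class,
                 bounds = bounds),
            class = "burn_plan")
}

#' Generate a synthetic set of burn plans
#'
#' Emulates the composition of an operational burn-plan collection: forest
#' and non-forest plans with per-variable acceptable ranges jittered around
#' class-typical values. All forest plans carry 100-h/1000-h fuel moisture
#' bounds; non-forest plans never do. The values are synthetic stand-ins for
#' real plan envelopes, not any published plan set.
#'
#' @param n_forest,n_nonforest number of plans per class (>= 1).
#' @param seed integer seed.
#' @return list of \code{\link{burn_plan}} objects (forest first).
#' @export
generate_burn_plans <- function(n_forest = 14, n_nonforest = 8, seed = 1L) {
  if (n_forest < 1 || n_nonforest < 1) stop("plan counts must be >= 1")
  base <- list(
    forest = list(temp = c(2, 30), rh = c(25, 55),
                  midflame_wind = c(0.4, 4.0), fm1 = c(4, 12),
                  fm10 = c(6, 14), fm100 = c(8, 18), fm1000 = c(10, 22),
                  ignition_component = c(5, 45)),
    `non-forest` = list(temp = c(2, 32), rh = c(20, 50),
                        midflame_wind = c(0.4, 4.5), fm1 = c(3, 10),
                        fm10 = c(5, 12), ignition_component = c(10, 60)))
  jit <- c(temp = 2, rh = 4, midflame_wind = 0.3, fm1 = 1.2, fm10 = 1.2,
           fm100 = 1.5, fm1000 = 2, ignition_component = 5)
  set.seed(.derive_seed(seed, "burnplans"))
  mk <- function(class, i) {
    b <- base[[class]]
    bounds <- lapply(names(b), function(v) {
      b[[v]] + runif(2, -jit[[v]], jit[[v]])
    })
    names(bounds) <- names(b)
    burn_plan(sprintf("%s-%02d", if (class == "forest") "F" else "NF", i),
              class, bounds)
  }
  c(lapply(seq_len(n_forest), function(i) mk("forest", i)),
    lapply(seq_len(n_nonforest), function(i) mk("non-forest", i)))
}

#' Median prescription envelope over a set of burn plans
#'
#' For each variable bounded by at least one plan of the requested class,
#' takes the median of the plan lower bounds and the median of the plan
#' upper bounds (independently; even plan counts use the usual
#' mean-of-middle-two median). Variables present in only some plans are
#' pooled over the plans that include them.
#'
#' @param plans list of \code{\link{burn_plan}} objects.
#' @param veg_class "forest", "non-forest", or "all" (pool every plan,
#'   used for the all-plans uniform definition variant).
#' @return object of class \code{prescription_envelope}: veg_class, bounds
#'   (named list of \code{c(lower, upper)}), contributing plan ids.
#' @export
median_envelope <- function(plans, veg_class = c("forest", "non-forest",
                                                 "all")) {
  veg_class <- match.arg(veg_class)
  stopifnot(all(vapply(plans, inherits, logical(1), "burn_plan")))
  sel <- if (veg_class == "all") plans
         else Filter(function(p) p$veg_class == veg_class, plans)
  if (!length(sel))
    stop("no plans of class '", veg_class, "' supplied")
  vars <- unique(unlist(lapply(sel, function(p) names(p$bounds))))
  vars <- RX_VARS[RX_VARS %in% vars]
  bounds <- lapply(vars, function(v) {
    bb <- do.call(rbind, lapply(sel, function(p) p$bounds[[v]]))
    c(median(bb[, 1]), median(bb[, 2]))
  })
  names(bounds) <- vars
  structure(list(veg_class = veg_class, bounds = bounds,
                 plans = vapply(sel, function(p) p$id, character(1))),
            class = "prescription_envelope")
}

#' @export
print.prescription_envelope <- function(x, ...) {
  cat(sprintf("<prescription_envelope> class '%s' from %d plans\n",
              x$veg_class, length(x$plans)))
  for (v in names(x$bounds))
    cat(sprintf("  %-19s [%.2f, %.2f]\n", v, x$bounds[[v]][1],
                x$bounds[[v]][2]))
  invisible(x)
}

#' Mid-flame wind speed from daily-mean 10 m wind
#'
#' Scales the daily-mean 10 m wind by 1.5 (afternoon peak relative to the
#' daily mean) and then by 0.4 (frictional reduction to mid-flame height):
#' a net factor of 0.6.
#'
#' @param wind10 daily-mean 10 m wind speed, m/s (>= 0).
#' @return mid-flame wind speed, m/s. Vectorised.
#' @export
midflame_wind <- function(wind10) {
  if (any(wind10 < 0)) stop("wind speed must be >= 0")
  wind10 * 1.5 * 0.4
}

#' Assemble the per-day evaluation fields for RxDay classification
#'
#' Collects, per cell-day, the quantities prescriptions bound at peak burning
#' conditions: daily maximum temperature, daily minimum relative humidity,
#' mid-flame wind, the four dead fuel moisture classes and the ignition
#' component. Fields absent from the fuel-moisture object are omitted (not
#' zero-filled).
#'
#' @param weather a \code{\link{weather_grid}}.
#' @param fm a \code{fuel_moisture_grid} on the same axes.
#' @return named list of [time, lat, lon] arrays keyed by prescription
#'   variable name.
#' @export
daily_evaluation <- function(weather, fm) {
  stopifnot(inherits(weather, "weather_grid"),
            inherits(fm, "fuel_moisture_grid"))
  if (!identical(weather$dates, fm$dates) ||
      !isTRUE(all.equal(weather$lat, fm$lat)) ||
      !isTRUE(all.equal(weather$lon, fm$lon)))
    stop("weather and fuel-moisture grids are not aligned")
  out <- list(temp = weather$tmax, rh = weather$rhmin,
              midflame_wind = midflame_wind(weather$wind10))
  for (v in c("fm1", "fm10", "fm100", "fm1000"))
    if (!is.null(fm[[v]])) out[[v]] <- fm[[v]]
  if (!is.null(fm$ic)) out$ignition_component <- fm$ic
  out
}

#' Classify a single evaluation vector against an envelope
#'
#' Binary in-prescription determination: TRUE iff every variable bounded by
#' the envelope satisfies lower <= value <= upper (inclusive). A variable
#' bounded by the envelope but absent from the vector is an error, never a
#' silent pass.
#'
#' @param v named numeric vector of evaluation values.
#' @param env a \code{\link{median_envelope}} result.
#' @return logical scalar.
#' @export
classify_rxday <- function(v, env) {
  stopifnot(inherits(env, "prescription_envelope"))
  need <- names(env$bounds)
  missing <- setdiff(need, names(v))
  if (length(missing))
    stop("evaluation vector lacks required variable(s): ",
         paste(missing, collapse = ", "))
  for (nm in need) {
    b <- env$bounds[[nm]]
    x <- v[[nm]]
    if (!is.finite(x)) stop("non-finite evaluation value for '", nm, "'")
    if (x < b[1] || x > b[2]) return(FALSE)
  }
  TRUE
}

# drop bounds from an envelope according to a definition variant
.variant_envelope <- function(env, variant) {
  drop <- switch(variant,
                 no_fuel_moisture = FM_VARS,
                 no_heavy_fuel_moisture = HEAVY_FM_VARS,
                 character(0))
  env$bounds <- env$bounds[setdiff(names(env$bounds), drop)]
  if (!length(env$bounds))
    stop("variant '", variant, "' leaves no bounded variable")
  env
}

# logical [T, lat, lon] array: all of env's bounds satisfied
.env_ok <- function(ev, env) {
  ok <- NULL
  for (nm in names(env$bounds)) {
    if (is.null(ev[[nm]]))
      stop("evaluation fields lack required variable '", nm, "'")
    b <- env$bounds[[nm]]
    this <- ev[[nm]] >= b[1] & ev[[nm]] <= b[2]
    ok <- if (is.null(ok)) this else ok & this
  }
  ok
}

#' Classify every grid-day as in or out of prescription
#'
#' Applies prescription envelopes over the whole grid under one of the
#' definition variants: \code{veg_aware} (forest envelope on forest cells,
#' non-forest envelope elsewhere -- the primary definition),
#' \code{forest_uniform} / \code{nonforest_uniform} /
#' \code{allplans_uniform} (one envelope everywhere, for sensitivity
#' analysis), \code{no_fuel_moisture} (veg-aware with all fuel moisture and
#' ignition-component bounds dropped: meteorology-only definition) and
#' \code{no_heavy_fuel_moisture} (veg-aware without the 100-h/1000-h
#' bounds). The first \code{spinup} days of the fuel-moisture grid are
#' excluded from the output.
#'
#' @param weather a \code{\link{weather_grid}}.
#' @param fm matching \code{fuel_moisture_grid}.
#' @param mask a \code{\link{generate_vegetation_mask}} result on the same
#'   lat/lon grid.
#' @param env_forest,env_nonforest class envelopes.
#' @param variant definition variant (see Details).
#' @param env_all pooled all-plans envelope; required for
#'   \code{allplans_uniform}.
#' @return a \code{\link{day_grid}} of RxDay flags (post-spin-up days only),
#'   labelled with the variant.
#' @export
rxday_grid <- function(weather, fm, mask, env_forest, env_nonforest,
                       variant = c("veg_aware", "forest_uniform",
                                   "nonforest_uniform", "allplans_uniform",
                                   "no_fuel_moisture",
                                   "no_heavy_fuel_moisture"),
                       env_all = NULL) {
  variant <- match.arg(variant)
  stopifnot(inherits(mask, "vegetation_mask"))
  if (!isTRUE(all.equal(mask$lat, weather$lat)) ||
      !isTRUE(all.equal(mask$lon, weather$lon)))
    stop("vegetation mask is not on the weather grid")
  ev <- daily_evaluation(weather, fm)
  nt <- length(weather$dates)

  flag <- switch(
    variant,
    forest_uniform = .env_ok(ev, env_forest),
    nonforest_uniform = .env_ok(ev, env_nonforest),
    allplans_uniform = {
      if (is.null(env_all))
        stop("variant 'allplans_uniform' requires env_all")
      .env_ok(ev, env_all)
    },
    {   # veg-aware family
      okf <- .env_ok(ev, .variant_envelope(env_forest, variant))
      okn <- .env_ok(ev, .variant_envelope(env_nonforest, variant))
      fmask <- aperm(array(mask$forest, c(dim(mask$forest), nt)), c(3, 1, 2))
      ifelse(fmask, okf, okn)
    })
  flag <- array(as.logical(flag), dim(ev$temp))

  keep <- seq_len(nt) > fm$spinup
  day_grid(weather$dates[keep], weather$lat, weather$lon,
           flag[keep, , , drop = FALSE], label = paste0("rxday:", variant))
}
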