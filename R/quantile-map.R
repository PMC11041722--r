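# Empirical quantile-mapping bias correction. Model-derived fire-danger
# metrics inherit biases from covariance and serial-correlation errors in the
# driving meteorology, so they are corrected against pseudo-observations by
# matching empirical quantiles over a common training period, per grid cell
# and (by default) per calendar-month pool; values beyond the training range
# are shifted by the constant offset at the extreme node, which preserves
# modelled change signals outside the training support.

#' Fit an empirical quantile map
#'
#' Computes paired sorted quantile tables of a model series and an
#' observation series at \code{n_quantiles} evenly spaced probabilities,
#' either pooled over all days or per calendar month.
#'
#' @param model_train,obs_train numeric series over a common training
#'   period (need not be paired day-by-day; only distributions are used).
#' @param dates Date vector for the training series (required for monthly
#'   pooling; both series must share it, so their lengths must match).
#' @param n_quantiles number of quantile nodes (default 100).
#' @param pooling "month" (seasonal bias structure, the default) or "all"
#'   (one pool; use for short series).
#' @return object of class \code{quantile_map}.
#' @export
fit_quantile_map <- function(model_train, obs_train, dates = NULL,
                             n_quantiles = 100,
                             pooling = c("month", "all")) {
  pooling <- match.arg(pooling)
  if (!length(model_train) || !length(obs_train))
    stop("training series must be nonempty")
  if (anyNA(model_train) || anyNA(obs_train))
    stop("training series must not contain NA")
  if (pooling == "month") {
    if (is.null(dates)) stop("monthly pooling requires 'dates'")
    if (length(dates) != length(model_train) ||
        length(dates) != length(obs_train))
      stop("with monthly pooling, model, obs and dates must be equal length")
    key <- format(as.Date(dates), "%m")
  } else {
    key <- rep("all", length(model_train))
    if (length(obs_train) != length(model_train)) {
      # pooled fit tolerates different lengths; quantiles only
      probs <- (seq_len(n_quantiles) - 0.5) / n_quantiles
      tab <- list(all = list(
        q_model = quantile(model_train, probs, names = FALSE, type = 7),
        q_obs = quantile(obs_train, probs, names = FALSE, type = 7)))
      return(structure(list(pooling = pooling, n_quantiles = n_quantiles,
                            tables = tab), class = "quantile_map"))
    }
  }
  probs <- (seq_len(n_quantiles) - 0.5) / n_quantiles
  pools <- sort(unique(key))
  tab <- lapply(pools, function(p) {
    i <- key == p
    list(q_model = quantile(model_train[i], probs, names = FALSE, type = 7),
         q_obs = quantile(obs_train[i], probs, names = FALSE, type = 7))
  })
  names(tab) <- pools
  structure(list(pooling = pooling, n_quantiles = n_quantiles, tables = tab),
            class = "quantile_map")
}

# transfer through one pool's table: linear interpolation between nodes,
# constant-offset extrapolation beyond the extreme nodes
.qmap_transfer <- function(qm, qo, x) {
  n <- length(qm)
  y <- numeric(length(x))
  lo <- x < qm[1]; hi <- x > qm[n]; mid <- !lo & !hi
  y[lo] <- x[lo] + (qo[1] - qm[1])
  y[hi] <- x[hi] + (qo[n] - qm[n])
  if (any(mid)) {
    if (qm[n] - qm[1] <= 0) {
      y[mid] <- x[mid] + (mean(qo) - qm[1])   # degenerate constant table
    } else {
      y[mid] <- approx(qm, qo, xout = x[mid], ties = mean)$y
    }
  }
  y
}

#' Apply a fitted quantile map
#'
#' Monotone transform of a series through the fitted quantile tables:
#' linear interpolation between nodes within the training support, constant
#' tail offsets outside it. Rank order is preserved within each pool.
#'
#' @param map a \code{\link{fit_quantile_map}} result.
#' @param x numeric series to correct.
#' @param dates Date vector for \code{x} (required for monthly pooling).
#' @return corrected numeric series, same length as \code{x}.
#' @export
apply_quantile_map <- function(map, x, dates = NULL) {
  stopifnot(inherits(map, "quantile_map"))
  if (map$pooling == "month") {
    if (is.null(dates)) stop("monthly pooling requires 'dates'")
    if (length(dates) != length(x)) stop("dates must match x")
    key <- format(as.Date(dates), "%m")
    out <- numeric(length(x))
    for (p in unique(key)) {
      if (is.null(map$tables[[p]]))
        stop("no fitted table for calendar month ", p)
      i <- key == p
      out[i] <- .qmap_transfer(map$tables[[p]]$q_model,
                               map$tables[[p]]$q_obs, x[i])
    }
    out
  } else {
    .qmap_transfer(map$tables$all$q_model, map$tables$all$q_obs, x)
  }
}

#' Bias-correct model-derived fuel moisture grids by quantile mapping
#'
#' Fits a per-cell (and per-month) quantile map between model and
#' pseudo-observed fuel-moisture metrics over a training period and applies
#' it to the model's full series. Correction targets the derived metrics,
#' not the raw weather. Corrected moistures are floored at 0 and the
#' ignition component is clipped to [0, 100].
#'
#' @param fm_model model-derived \code{fuel_moisture_grid}.
#' @param fm_obs pseudo-observed \code{fuel_moisture_grid} on the same
#'   lat/lon grid.
#' @param fields metric names to correct (default the prescription inputs).
#' @param train_years integer years defining the training overlap; default
#'   the intersection of the two grids' calendar years.
#' @param n_quantiles,pooling passed to \code{\link{fit_quantile_map}}.
#' @return corrected \code{fuel_moisture_grid} (model axes).
#' @export
bias_correct_fm <- function(fm_model, fm_obs,
                            fields = c("fm1", "fm10", "fm100", "fm1000",
                                       "ic"),
                            train_years = NULL, n_quantiles = 100,
                            pooling = c("month", "all")) {
  pooling <- match.arg(pooling)
  stopifnot(inherits(fm_model, "fuel_moisture_grid"),
            inherits(fm_obs, "fuel_moisture_grid"))
  if (!isTRUE(all.equal(fm_model$lat, fm_obs$lat)) ||
      !isTRUE(all.equal(fm_model$lon, fm_obs$lon)))
    stop("model and observation grids differ")
  yr_m <- as.integer(format(fm_model$dates, "%Y"))
  yr_o <- as.integer(format(fm_obs$dates, "%Y"))
  if (is.null(train_years)) train_years <- intersect(yr_m, yr_o)
  if (!length(train_years)) stop("no training overlap between the grids")
  itm <- yr_m %in% train_years
  ito <- yr_o %in% train_years
  if (!any(itm) || !any(ito)) stop("empty training period")
  if (sum(itm) != sum(ito))
    stop("training periods must cover the same dates in both grids")

  out <- fm_model
  ncell <- length(fm_model$lat) * length(fm_model$lon)
  nt <- length(fm_model$dates)
  for (f in fields) {
    if (is.null(fm_model[[f]])) stop("model grid lacks field '", f, "'")
    mdl <- matrix(fm_model[[f]], nt, ncell)
    obs <- matrix(fm_obs[[f]], length(fm_obs$dates), ncell)
    cor <- mdl
    for (j in seq_len(ncell)) {
      map <- fit_quantile_map(mdl[itm, j], obs[ito, j],
                              dates = fm_model$dates[itm],
                              n_quantiles = n_quantiles, pooling = pooling)
      cor[, j] <- apply_quantile_map(map, mdl[, j], dates = fm_model$dates)
    }
    cor <- pmax(cor, 0)
    if (f == "ic") cor <- pmin(cor, 100)
    out[[f]] <- array(cor, dim(fm_model[[f]]))
  }
  out
}
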