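# End-to-end driver: synthetic (or file) weather -> NFDRS metrics ->
# [quantile-mapping bias correction for model members] -> RxDay
# classification -> seasonal/annual counts, regional series and trends;
# air-stagnation counts in parallel. Fully deterministic given the config
# (which carries the master seed); a JSON manifest embeds the whole config
# so any run can be reproduced from its own output directory.

#' Build a pipeline configuration
#'
#' Collects every knob of the end-to-end analysis. Either programmatic
#' (pass arguments) or loaded from YAML/JSON via \code{\link{read_pipeline_config}}.
#'
#' @param spec \code{\link{climate_spec}} arguments as a list (the seed is
#'   overridden by \code{seed}), or a ready \code{climate_spec}.
#' @param seed master seed for every source of randomness.
#' @param forest_fraction target forest fraction of the vegetation mask.
#' @param n_forest_plans,n_nonforest_plans synthetic burn-plan counts.
#' @param plans_file optional path to a burn-plan JSON (overrides the
#'   synthetic plan set).
#' @param variant RxDay definition variant (see \code{\link{rxday_grid}}).
#' @param spinup fuel-moisture spin-up days.
#' @param seasons aggregations to compute.
#' @param regions named list of \code{\link{region_box}}; default
#'   \code{\link{wus_regions}()}.
#' @param ensemble NULL, or a list with \code{n_members} and optionally
#'   \code{bias_sd} (named per-variable sd of member climatology biases),
#'   \code{trend_sd} (same for trend perturbations), and
#'   \code{agreement_threshold} (accumulated-change magnitude for the
#'   member-agreement count).
#' @param bias_correction logical: quantile-map member fuel moistures
#'   against the pseudo-observed run (only relevant with an ensemble).
#' @param out_dir output directory.
#' @return object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(spec = list(), seed = 1L, forest_fraction = 0.5,
                            n_forest_plans = 14, n_nonforest_plans = 8,
                            plans_file = NULL,
                            variant = "veg_aware", spinup = 90L,
                            seasons = c("annual", "DJF", "MAM", "JJA",
                                        "SON"),
                            regions = wus_regions(),
                            ensemble = NULL, bias_correction = TRUE,
                            out_dir = tempfile("rxwindows_run_")) {
  if (inherits(spec, "climate_spec")) spec <- unclass(spec)
  structure(list(spec = spec, seed = as.integer(seed),
                 forest_fraction = forest_fraction,
                 n_forest_plans = n_forest_plans,
                 n_nonforest_plans = n_nonforest_plans,
                 plans_file = plans_file, variant = variant,
                 spinup = as.integer(spinup), seasons = seasons,
                 regions = regions, ensemble = ensemble,
                 bias_correction = isTRUE(bias_correction),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path config file; top-level keys as in
#'   \code{\link{pipeline_config}}. Regions may be given as
#'   \code{name: {lat_range: [a,b], lon_range: [a,b]}} maps.
#' @return a \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$regions)) {
    raw$regions <- lapply(seq_along(raw$regions), function(i) {
      r <- raw$regions[[i]]
      region_box(names(raw$regions)[i], as.numeric(unlist(r$lat_range)),
                 as.numeric(unlist(r$lon_range)))
    })
    names(raw$regions) <- vapply(raw$regions, function(r) r$name,
                                 character(1))
  }
  if (!is.null(raw$spec)) {
    for (nm in c("clim")) if (!is.null(raw$spec[[nm]]))
      raw$spec[[nm]] <- lapply(raw$spec[[nm]], function(x) unlist(x))
    for (nm in c("trend", "sd", "lat_gradient", "wet_prob"))
      if (!is.null(raw$spec[[nm]])) raw$spec[[nm]] <- unlist(raw$spec[[nm]])
  }
  do.call(pipeline_config, raw)
}

.build_spec <- function(config) {
  args <- config$spec
  args$seed <- config$seed
  do.call(climate_spec, args)
}

# regional series for every (season, region); long data.frame
.regional_table <- function(dg, seasons, regions, land_mask = NULL) {
  out <- list()
  for (s in seasons) {
    cs <- seasonal_counts(dg, s)
    for (rn in names(regions)) {
      rm <- regional_mean(cs, regions[[rn]], land_mask)
      out[[length(out) + 1L]] <- data.frame(
        year = rm$year, season = s, region = rn, value = rm$value)
    }
  }
  do.call(rbind, out)
}

.trend_table <- function(regional) {
  keys <- unique(regional[, c("season", "region")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- regional[regional$season == keys$season[i] &
                      regional$region == keys$region[i], ]
    tr <- linear_trend(sub$value, sub$year)
    list(season = keys$season[i], region = keys$region[i],
         slope = tr$slope, accumulated = tr$accumulated,
         percent = tr$percent, p_value = tr$p_value, n_years = tr$n_years)
  })
}

#' Run the full burn-window pipeline
#'
#' Executes every stage on synthetic data defined by the config: weather
#' generation, vegetation mask, burn plans and median envelopes, NFDRS fuel
#' moisture, RxDay classification, seasonal/annual counts, regional series
#' and OLS trends, air-stagnation counts, and (optionally) a pseudo-model
#' ensemble with quantile-mapping bias correction and member agreement.
#' Writes \code{rx.nc}, \code{lls.nc}, \code{regional_counts.csv},
#' \code{trends.json}, \code{plans.json} and \code{manifest.json} to the
#' output directory. Two runs with the same config produce byte-identical
#' text artifacts.
#'
#' @param config a \code{\link{pipeline_config}} (or path to a YAML/JSON
#'   config file).
#' @return invisibly, a list with the in-memory results (weather, fm, rx,
#'   regional tables, trends, lls, ensemble summary, file paths).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()

  spec <- .build_spec(config)
  weather <- generate_weather_grid(spec)
  mask <- generate_vegetation_mask(weather$lat, weather$lon,
                                   config$forest_fraction,
                                   seed = config$seed)
  plans <- if (!is.null(config$plans_file))
    read_burn_plans(config$plans_file)
  else generate_burn_plans(config$n_forest_plans, config$n_nonforest_plans,
                           seed = config$seed)
  env_f <- median_envelope(plans, "forest")
  env_n <- median_envelope(plans, "non-forest")
  env_a <- median_envelope(plans, "all")

  fm <- compute_fuel_moisture(weather, spinup = config$spinup)
  rx <- rxday_grid(weather, fm, mask, env_f, env_n,
                   variant = config$variant, env_all = env_a)

  regional <- .regional_table(rx, config$seasons, config$regions,
                              land_mask = NULL)
  trends <- .trend_table(regional)

  lls <- lls_grid(weather)
  lls_regional <- .regional_table(lls, config$seasons, config$regions)
  lls_trends <- .trend_table(lls_regional)

  ens_summary <- NULL
  if (!is.null(config$ensemble)) {
    ne <- config$ensemble$n_members
    set.seed(.derive_seed(config$seed, "ensemble-perturbations"))
    draw <- function(sdv) if (is.null(sdv)) vector("list", ne) else
      lapply(seq_len(ne), function(i)
        setNames(rnorm(length(sdv), 0, sdv), names(sdv)))
    ens <- ensemble_spec(ne, bias = draw(config$ensemble$bias_sd),
                         trend_perturb = draw(config$ensemble$trend_sd))
    members <- generate_ensemble(spec, ens)
    member_series <- lapply(members, function(w) {
      fmm <- compute_fuel_moisture(w, spinup = config$spinup)
      if (config$bias_correction)
        fmm <- bias_correct_fm(fmm, fm)
      rxm <- rxday_grid(w, fmm, mask, env_f, env_n,
                        variant = config$variant, env_all = env_a)
      regional_mean(seasonal_counts(rxm, "annual"), config$regions[[1]])
    })
    ens_summary <- ensemble_statistics(
      member_series, threshold = config$ensemble$agreement_threshold)
  }

  paths$rx <- file.path(config$out_dir, "rx.nc")
  write_day_grid_netcdf(rx, paths$rx)
  paths$lls <- file.path(config$out_dir, "lls.nc")
  write_day_grid_netcdf(lls, paths$lls)
  paths$regional <- file.path(config$out_dir, "regional_counts.csv")
  both <- rbind(cbind(metric = "rxdays", regional),
                cbind(metric = "lls", lls_regional))
  write.csv(both, paths$regional, row.names = FALSE)
  paths$trends <- file.path(config$out_dir, "trends.json")
  jsonlite::write_json(list(rxdays = trends, lls = lls_trends),
                       paths$trends, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths$plans <- file.path(config$out_dir, "plans.json")
  write_burn_plans(plans, paths$plans)
  paths$manifest <- file.path(config$out_dir, "manifest.json")
  manifest <- list(package = "rxwindows",
                   version = as.character(packageVersion("rxwindows")),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."),
                   seed = config$seed,
                   config = .config_payload(config),
                   artifacts = lapply(paths[names(paths) != "manifest"],
                                      basename))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(weather = weather, mask = mask, plans = plans,
                 envelopes = list(forest = env_f, nonforest = env_n,
                                  all = env_a),
                 fm = fm, rx = rx, regional = regional, trends = trends,
                 lls = lls, lls_regional = lls_regional,
                 lls_trends = lls_trends, ensemble = ens_summary,
                 paths = paths))
}

# config as plain lists for JSON round-tripping; named atomic vectors must
# become lists or jsonlite drops their names
.as_json_safe <- function(x) {
  if (inherits(x, "Date")) return(format(x))
  if (is.atomic(x) && !is.null(names(x))) return(as.list(x))
  if (is.list(x)) return(lapply(x, .as_json_safe))
  x
}

.config_payload <- function(config) {
  out <- unclass(config)
  out$regions <- lapply(out$regions, function(r)
    list(lat_range = r$lat_range, lon_range = r$lon_range))
  out$spec <- lapply(out$spec, .as_json_safe)
  out$ensemble <- .as_json_safe(out$ensemble)
  out$out_dir <- NULL
  out
}

#' Re-run a pipeline from its manifest
#'
#' Reads the manifest written by \code{\link{run_pipeline}} and re-executes
#' the pipeline with the embedded config, reproducing all numeric outputs.
#'
#' @param manifest_path path to a \code{manifest.json}.
#' @param out_dir output directory for the re-run (default a fresh tempdir).
#' @return as \code{\link{run_pipeline}}.
#' @export
rerun_from_manifest <- function(manifest_path,
                                out_dir = tempfile("rxwindows_rerun_")) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  cfg <- man$config
  cfg$regions <- lapply(cfg$regions, function(r)
    list(lat_range = as.numeric(unlist(r$lat_range)),
         lon_range = as.numeric(unlist(r$lon_range))))
  cfg$regions <- lapply(names(cfg$regions), function(nm)
    region_box(nm, cfg$regions[[nm]]$lat_range, cfg$regions[[nm]]$lon_range))
  names(cfg$regions) <- vapply(cfg$regions, function(r) r$name, character(1))
  for (nm in c("clim")) if (!is.null(cfg$spec[[nm]]))
    cfg$spec[[nm]] <- lapply(cfg$spec[[nm]], unlist)
  for (nm in c("trend", "sd", "lat_gradient", "wet_prob"))
    if (!is.null(cfg$spec[[nm]])) cfg$spec[[nm]] <- unlist(cfg$spec[[nm]])
  # JSON round-trips NULL fields as empty lists; normalise them back
  for (nm in c("plans_file", "ensemble"))
    if (!length(cfg[[nm]])) cfg[nm] <- list(NULL)
  if (!is.null(cfg$ensemble)) {
    cfg$ensemble <- as.list(cfg$ensemble)
    for (nm in c("bias_sd", "trend_sd"))
      if (!is.null(cfg$ensemble[[nm]]))
        cfg$ensemble[[nm]] <- unlist(cfg$ensemble[[nm]])
  }
  cfg$out_dir <- out_dir
  run_pipeline(do.call(pipeline_config, cfg))
}
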