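# Median envelopes, mid-flame wind scaling, binary classification and the
# gridded RxDay definition variants.

test_that("median envelopes take per-variable medians of plan bounds", {
  mk <- function(lo, hi, id) burn_plan(id, "forest", list(rh = c(lo, hi)))
  env <- median_envelope(list(mk(20, 60, "a"), mk(25, 62, "b"),
                              mk(30, 70, "c")), "forest")
  expect_equal(env$bounds$rh, c(25, 62))
  # even counts: mean of the middle two
  env2 <- median_envelope(list(mk(20, 60, "a"), mk(30, 70, "b")), "forest")
  expect_equal(env2$bounds$rh, c(25, 65))
  expect_error(median_envelope(list(), "forest"))
})

test_that("variables present in only some plans pool over those plans", {
  p1 <- burn_plan("a", "forest", list(rh = c(20, 60), fm1000 = c(10, 20)))
  p2 <- burn_plan("b", "forest", list(rh = c(30, 70)))
  env <- median_envelope(list(p1, p2), "forest")
  expect_equal(env$bounds$fm1000, c(10, 20))
  expect_equal(env$bounds$rh, c(25, 65))
})

test_that("non-forest envelopes never carry heavy fuel moisture bounds", {
  expect_error(burn_plan("x", "non-forest", list(fm100 = c(5, 10))),
               "non-forest")
  plans <- sample_plans()
  env <- median_envelope(plans, "non-forest")
  expect_false(any(c("fm100", "fm1000") %in% names(env$bounds)))
  envf <- median_envelope(plans, "forest")
  expect_true(all(c("fm100", "fm1000") %in% names(envf$bounds)))
})

test_that("mid-flame wind is the 10 m wind scaled by 1.5 then 0.4", {
  expect_equal(midflame_wind(10), 6)
  expect_equal(midflame_wind(0), 0)
  a <- runif(20, 0, 10); b <- runif(20, 0, 10)
  expect_equal(midflame_wind(a + b), midflame_wind(a) + midflame_wind(b))
  expect_error(midflame_wind(-1), "wind")
})

test_that("classification is an inclusive-bound conjunction", {
  env <- median_envelope(list(burn_plan("a", "forest",
                                        list(temp = c(5, 30),
                                             rh = c(20, 60),
                                             fm1 = c(4, 12)))), "forest")
  inside <- c(temp = 20, rh = 40, fm1 = 8)
  expect_true(classify_rxday(inside, env))
  one_low <- inside; one_low["rh"] <- 19
  expect_false(classify_rxday(one_low, env))
  at_upper <- inside; at_upper["temp"] <- 30
  expect_true(classify_rxday(at_upper, env))
  at_lower <- inside; at_lower["fm1"] <- 4
  expect_true(classify_rxday(at_lower, env))
})

test_that("a bounded variable missing from the vector errors, never passes", {
  env <- median_envelope(list(burn_plan("a", "forest",
                                        list(fm1000 = c(10, 20)))), "forest")
  expect_error(classify_rxday(c(temp = 20), env), "fm1000")
})

test_that("evaluation fields carry peak-burning quantities, not daily means", {
  w <- generate_weather_grid(tiny_spec())
  fm <- compute_fuel_moisture(w, spinup = 30)
  ev <- daily_evaluation(w, fm)
  expect_identical(ev$temp, w$tmax)
  expect_identical(ev$rh, w$rhmin)
  expect_equal(ev$midflame_wind, w$wind10 * 0.6, tolerance = 1e-12)
  expect_identical(ev$fm1000, fm$fm1000)
})

test_that("gridded classification equals the per-cell scalar oracle", {
  w <- generate_weather_grid(tiny_spec(seed = 12L))
  fm <- compute_fuel_moisture(w, spinup = 60)
  plans <- sample_plans()
  ef <- median_envelope(plans, "forest")
  en <- median_envelope(plans, "non-forest")
  mask <- generate_vegetation_mask(w$lat, w$lon, 0.5, seed = 9)
  rx <- rxday_grid(w, fm, mask, ef, en, "veg_aware")
  ev <- daily_evaluation(w, fm)
  keep <- which(seq_along(w$dates) > fm$spinup)
  set.seed(1)
  for (rep in 1:200) {
    t0 <- sample(seq_along(keep), 1)
    i <- sample(seq_along(w$lat), 1); j <- sample(seq_along(w$lon), 1)
    v <- vapply(ev, function(a) a[keep[t0], i, j], numeric(1))
    env <- if (mask$forest[i, j]) ef else en
    expect_identical(rx$flag[t0, i, j], classify_rxday(v, env))
  }
})

test_that("uniform variants and an all-forest mask coincide", {
  w <- generate_weather_grid(tiny_spec(seed = 13L))
  fm <- compute_fuel_moisture(w, spinup = 60)
  plans <- sample_plans()
  ef <- median_envelope(plans, "forest")
  en <- median_envelope(plans, "non-forest")
  all_forest <- generate_vegetation_mask(w$lat, w$lon, 1, seed = 1)
  rx_aware <- rxday_grid(w, fm, all_forest, ef, en, "veg_aware")
  rx_unif <- rxday_grid(w, fm, all_forest, ef, en, "forest_uniform")
  expect_identical(rx_aware$flag, rx_unif$flag)
  # all-plans variant needs the pooled envelope
  expect_error(rxday_grid(w, fm, all_forest, ef, en, "allplans_uniform"),
               "env_all")
  ea <- median_envelope(plans, "all")
  rx_all <- rxday_grid(w, fm, all_forest, ef, en, "allplans_uniform",
                       env_all = ea)
  expect_s3_class(rx_all, "day_grid")
})

test_that("dropping constraints never unmakes an RxDay", {
  w <- generate_weather_grid(tiny_spec(seed = 14L))
  fm <- compute_fuel_moisture(w, spinup = 60)
  plans <- sample_plans()
  ef <- median_envelope(plans, "forest")
  en <- median_envelope(plans, "non-forest")
  mask <- generate_vegetation_mask(w$lat, w$lon, 0.6, seed = 2)
  rx <- rxday_grid(w, fm, mask, ef, en, "veg_aware")
  rx_noheavy <- rxday_grid(w, fm, mask, ef, en, "no_heavy_fuel_moisture")
  rx_nofm <- rxday_grid(w, fm, mask, ef, en, "no_fuel_moisture")
  expect_true(all(rx_noheavy$flag >= rx$flag))
  expect_true(all(rx_nofm$flag >= rx_noheavy$flag))
})

test_that("burn plans round-trip through JSON", {
  plans <- sample_plans()
  path <- tempfile(fileext = ".json")
  write_burn_plans(plans, path)
  back <- read_burn_plans(path)
  expect_equal(length(back), length(plans))
  for (i in seq_along(plans)) {
    expect_identical(back[[i]]$id, plans[[i]]$id)
    expect_identical(back[[i]]$veg_class, plans[[i]]$veg_class)
    expect_equal(back[[i]]$bounds, plans[[i]]$bounds, tolerance = 1e-12)
  }
  unlink(path)
})
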