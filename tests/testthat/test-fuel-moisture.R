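# NFDRS chain: EMC polynomial regimes, day length, weighting, duration
# model, fine-fuel scalings, heavy-fuel recursions, ignition component and
# the gridded computation against a scalar per-cell oracle.

test_that("EMC matches the regime polynomials and their contracts", {
  # rh = 0 collapses regime 1 to its intercept
  expect_equal(equilibrium_moisture_content(70, 0), 0.03229)
  expect_equal(equilibrium_moisture_content(-10, 0), 0.03229)
  # monotone increasing in RH at fixed T across the physical range
  rh <- seq(0, 100, by = 0.5)
  for (tf in c(30, 70, 110)) {
    e <- equilibrium_moisture_content(tf, rh)
    within <- split(e, cut(rh, c(-Inf, 9.99, 50, Inf)))
    for (seg in within) expect_true(all(diff(seg) > 0))
  }
  expect_gt(equilibrium_moisture_content(70, 90),
            equilibrium_moisture_content(70, 20))
  # regime seams are continuous to well under a percentage point
  for (tf in seq(30, 110, by = 10)) {
    expect_lt(abs(equilibrium_moisture_content(tf, 10 - 1e-9) -
                    equilibrium_moisture_content(tf, 10 + 1e-9)), 1)
    expect_lt(abs(equilibrium_moisture_content(tf, 50 - 1e-9) -
                    equilibrium_moisture_content(tf, 50 + 1e-9)), 1)
  }
  expect_error(equilibrium_moisture_content(70, 101), "rh")
  expect_error(equilibrium_moisture_content(70, -2), "rh")
})

test_that("day length follows solar geometry", {
  expect_equal(daylength_hours(0, 1), 12, tolerance = 0.2)
  expect_equal(daylength_hours(0, 180), 12, tolerance = 0.2)
  expect_equal(daylength_hours(45, 80), 12, tolerance = 0.3)  # equinox
  expect_gt(daylength_hours(45, 172), daylength_hours(45, 355))
  dl <- daylength_hours(seq(-60, 60, by = 5), 100)
  expect_true(all(dl > 0 & dl < 24))
  expect_error(daylength_hours(70, 100), "polar")
})

test_that("daylight weighting of EMC behaves at its limits", {
  expect_equal(emc_bar(12, 12, 10), 12)
  expect_equal(emc_bar(6, 18, 12), 12)       # arithmetic mean
  expect_equal(emc_bar(6, 18, 24), 6)        # all daylight
  e <- emc_bar(5, 15, 9)
  expect_true(e > 5 && e < 15)
  expect_error(emc_bar(5, 15, 25), "daylight")
})

test_that("precipitation duration is a monotone capped step model", {
  expect_equal(precip_duration(0), 0)
  expect_equal(precip_duration(0.2), 0)      # below trace
  expect_equal(precip_duration(0.3), 1)
  expect_gte(precip_duration(10), precip_duration(2))
  expect_equal(precip_duration(500), 8)      # cap
  p <- seq(0, 60, by = 0.25)
  expect_true(all(diff(precip_duration(p)) >= 0))
  expect_error(precip_duration(-1), "precip")
})

test_that("fine fuel moisture scales EMC by the fixed coefficients", {
  expect_equal(fm1(0), 0)
  expect_equal(fm10(0), 0)
  expect_equal(fm1(10), 10.3)
  expect_equal(fm10(10), 12.8)
  expect_gt(fm10(7.3), fm1(7.3))
})

test_that("heavy-fuel steps contract toward the boundary at the closed-form rate", {
  expect_equal(fm100_step(20, 20), 20)
  expect_equal(fm1000_step(20, 20), 20)
  s <- fm100_step(10, 20)
  expect_true(s > 10 && s < 20)
  # geometric decay: |fm_n - B| = |init - B| * r^n
  for (cls in c("fm100", "fm1000")) {
    step <- if (cls == "fm100") fm100_step else fm1000_step
    r <- if (cls == "fm100") 0.87 * exp(-0.24) else 0.82 * exp(-0.168)
    B <- 18; x <- 4
    for (n in 1:30) x <- step(x, B)
    expect_equal(abs(x - B), abs(4 - B) * r^30, tolerance = 1e-9)
  }
  expect_error(fm100_step(-1, 5), "moisture")
})

test_that("ignition component honours its range and monotonicity contracts", {
  fm <- seq(0, 45, by = 0.5)
  tf <- seq(10, 115, by = 5)
  grid <- expand.grid(fm = fm, tf = tf)
  ic <- ignition_component(grid$fm, grid$tf)
  expect_true(all(ic >= 0 & ic <= 100))
  expect_true(all(ic == floor(ic)))
  # nonincreasing in fuel moisture at fixed temperature
  for (t1 in c(40, 75, 110)) {
    v <- ignition_component(fm, t1)
    expect_true(all(diff(v) <= 0))
  }
  # nondecreasing in temperature at fixed fuel moisture
  for (f1 in c(2, 8, 15)) {
    v <- ignition_component(f1, tf)
    expect_true(all(diff(v) >= 0))
  }
  expect_gt(ignition_component(3, 95), ignition_component(20, 95))
  # saturated fuels cannot ignite
  expect_true(all(ignition_component(seq(35, 60, 1), 115) == 0))
})

test_that("constant forcing drives fm100/fm1000 to their analytic fixed points", {
  w <- constant_weather(n_days = 400)
  fmg <- compute_fuel_moisture(w, spinup = 90)
  # fixed point equals the (constant) boundary value
  tf_max <- 25 * 9 / 5 + 32; tf_min <- 10 * 9 / 5 + 32
  e_min <- equilibrium_moisture_content(tf_max, 30)
  e_max <- equilibrium_moisture_content(tf_min, 70)
  doy <- as.integer(strftime(w$dates, "%j"))
  dl <- daylength_hours(w$lat[1], doy)
  eb <- emc_bar(e_min, e_max, dl)
  # day length varies seasonally, so compare to the day's own boundary
  expect_equal(fmg$fm100[400, 1, 1], fm100_boundary(eb[400], 0),
               tolerance = 0.05)
  expect_equal(fmg$fm1000[400, 1, 1], fm1000_boundary(eb[400], 0),
               tolerance = 0.1)
})

test_that("gridded fuel moisture equals the scalar per-cell oracle exactly", {
  w <- generate_weather_grid(tiny_spec(seed = 21L))
  fmg <- compute_fuel_moisture(w, spinup = 90)
  for (i in c(1, 3)) for (j in c(2, 3)) {
    oracle <- fm_cell_oracle(w, i, j)
    expect_identical(fmg$fm100[, i, j], oracle$fm100)
    expect_identical(fmg$fm1000[, i, j], oracle$fm1000)
  }
})

test_that("two initialisations forget each other within the spin-up window", {
  w <- generate_weather_grid(tiny_spec(seed = 33L))
  nt <- length(w$dates)
  doy <- as.integer(strftime(w$dates, "%j"))
  e_min <- equilibrium_moisture_content(c_to_f(w$tmax[, 1, 1]),
                                        w$rhmin[, 1, 1])
  e_max <- equilibrium_moisture_content(c_to_f(w$tmin[, 1, 1]),
                                        w$rhmax[, 1, 1])
  eb <- emc_bar(e_min, e_max, daylength_hours(w$lat[1], doy))
  b <- fm100_boundary(eb, precip_duration(w$precip[, 1, 1]))
  run <- function(init) {
    x <- numeric(nt); prev <- init
    for (t in seq_len(nt)) { prev <- fm100_step(prev, b[t]); x[t] <- prev }
    x
  }
  gap <- abs(run(1) - run(60))
  expect_true(all(diff(gap) <= 1e-12))         # monotone shrinkage
  expect_lt(gap[90], 0.01)
})

test_that("fuel moisture outputs are nonnegative, finite and local", {
  w <- generate_weather_grid(tiny_spec(seed = 4L))
  fmg <- compute_fuel_moisture(w, spinup = 30)
  for (f in c("emc_bar", "fm1", "fm10", "fm100", "fm1000", "ic")) {
    expect_true(all(is.finite(fmg[[f]])))
    expect_true(all(fmg[[f]] >= 0))
  }
  expect_true(all(fmg$ic <= 100))
  expect_error(compute_fuel_moisture(w, spinup = length(w$dates)),
               "exceed")
})
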