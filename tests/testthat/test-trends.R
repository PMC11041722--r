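# Seasonal aggregation calendars, regional averaging, OLS trends, running
# means, epoch differences, ensemble agreement and interannual variability.

all_true_grid <- function(start, end) {
  dates <- seq(as.Date(start), as.Date(end), by = "day")
  day_grid(dates, lat = c(35, 40), lon = c(240, 245),
           array(TRUE, c(length(dates), 2, 2)), label = "all")
}

test_that("seasonal counts follow the calendar", {
  g <- all_true_grid("1985-01-01", "1986-12-31")
  ann <- seasonal_counts(g, "annual")
  expect_identical(ann$year, 1985:1986)
  expect_true(all(ann$counts == 365L))
  jja <- seasonal_counts(g, "JJA")
  expect_true(all(jja$counts == 92L))
  # first DJF lacks its December and is dropped; DJF 1986 has 90 days
  djf <- seasonal_counts(g, "DJF")
  expect_identical(djf$year, 1986L)
  expect_true(all(djf$counts == 90L))
  # DJF spanning a leap February counts 91
  gl <- all_true_grid("1987-12-01", "1988-03-10")
  djf_leap <- seasonal_counts(gl, "DJF")
  expect_identical(djf_leap$year, 1988L)
  expect_true(all(djf_leap$counts == 91L))
})

test_that("random flags tally identically to a brute-force masked count", {
  set.seed(21)
  dates <- seq(as.Date("1990-01-01"), as.Date("1992-12-31"), by = "day")
  flag <- array(runif(length(dates) * 4) < 0.3, c(length(dates), 2, 2))
  g <- day_grid(dates, c(35, 40), c(240, 245), flag, "rand")
  for (season in c("annual", "MAM", "SON")) {
    cs <- seasonal_counts(g, season)
    mo <- as.integer(format(dates, "%m"))
    sel <- switch(season, annual = rep(TRUE, length(dates)),
                  MAM = mo %in% 3:5, SON = mo %in% 9:11)
    for (k in seq_along(cs$year)) {
      yr <- as.integer(format(dates, "%Y"))
      rows <- sel & yr == cs$year[k]
      expect_equal(cs$counts[k, 1, 2], sum(flag[rows, 1, 2]))
    }
  }
})

test_that("regional means are cosine-latitude weighted over the box", {
  dates <- seq(as.Date("2000-01-01"), as.Date("2001-12-31"), by = "day")
  flag <- array(FALSE, c(length(dates), 2, 1))
  flag[, 1, 1] <- TRUE                       # southern band always flagged
  g <- day_grid(dates, c(30, 60), c(240), flag, "band")
  cs <- seasonal_counts(g, "annual")
  box <- region_box("all", c(25, 65), c(235, 245))
  got <- regional_mean(cs, box)$value[1]
  w1 <- cos(30 * pi / 180); w2 <- cos(60 * pi / 180)
  expect_equal(got, (366 * w1 + 0 * w2) / (w1 + w2), tolerance = 1e-10)
  # uniform fields average to the field value regardless of weights
  gu <- all_true_grid("2000-01-01", "2000-12-31")
  csu <- seasonal_counts(gu, "annual")
  expect_equal(regional_mean(csu, region_box("b", c(30, 45),
                                             c(235, 250)))$value, 366)
  expect_error(regional_mean(cs, region_box("off", c(0, 10), c(0, 10))),
               "overlap")
  # land mask restricts the average
  lm2 <- matrix(c(TRUE, FALSE), 2, 1)
  expect_equal(regional_mean(cs, box, land_mask = lm2)$value[1], 366)
})

test_that("OLS trend is exact on noiseless series and consistent", {
  years <- 1981:2020
  y <- 2 + 0.5 * (years - 1981)
  tr <- linear_trend(y, years)
  expect_equal(tr$slope, 0.5, tolerance = 1e-12)
  expect_equal(tr$accumulated, 19.5, tolerance = 1e-12)
  expect_equal(tr$percent * tr$baseline / 100, tr$accumulated,
               tolerance = 1e-9)
  flat <- linear_trend(rep(3, 10), 2001:2010)
  expect_equal(flat$slope, 0)
  expect_equal(flat$accumulated, 0)
  expect_error(linear_trend(c(1, 2), 1:2), "3 years")
  # percent change against the period mean on demand
  trm <- linear_trend(y, years, baseline = "mean")
  expect_equal(trm$baseline, mean(y))
})

test_that("trend of regional mean equals regional mean of cell trends", {
  set.seed(22)
  yrs <- 2001:2030
  a <- 10 + 0.3 * (yrs - 2001) + rnorm(30)
  b <- 20 - 0.1 * (yrs - 2001) + rnorm(30)
  w <- c(0.7, 0.3)
  lhs <- linear_trend(w[1] * a + w[2] * b, yrs)$slope
  rhs <- w[1] * linear_trend(a, yrs)$slope + w[2] * linear_trend(b, yrs)$slope
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("running mean smooths with truncated end windows", {
  x <- 1:10
  rm5 <- running_mean(x, 5)
  expect_equal(rm5[3:8], x[3:8])             # interior of a linear series
  expect_equal(rm5[1], mean(x[1:3]))
  expect_equal(rm5[10], mean(x[8:10]))
  expect_equal(running_mean(rep(7, 6), 5), rep(7, 6))
  imp <- c(0, 0, 0, 0, 5, 0, 0, 0, 0)
  expect_equal(running_mean(imp, 5)[3:7], rep(1, 5))
  expect_error(running_mean(1:3, 0), "window")
})

test_that("epoch differences equal per-cell mean differences", {
  set.seed(23)
  yrs <- 1981:2000
  counts <- array(rpois(20 * 4, 30), c(20, 2, 2))
  cs <- structure(list(year = yrs, counts = counts, season = "annual",
                       lat = c(35, 40), lon = c(240, 245)),
                  class = "count_series")
  d <- epoch_difference(cs, 1981:1990, 1991:2000)
  for (i in 1:2) for (j in 1:2)
    expect_equal(d[i, j], mean(counts[11:20, i, j]) -
                   mean(counts[1:10, i, j]))
  expect_equal(suppressWarnings(epoch_difference(cs, 1981:2000, 1981:2000)),
               matrix(0, 2, 2))
  expect_warning(epoch_difference(cs, 1981:1991, 1991:2000), "overlap")
  # a uniform shift appears exactly
  cs2 <- cs; cs2$counts[11:20, , ] <- cs$counts[11:20, , ] - 5
  expect_equal(epoch_difference(cs2, 1981:1990, 1991:2000), d - 5)
})

test_that("interannual SD is the sample standard deviation per cell", {
  alt <- rep(c(10, 20), 10)                  # n = 20 alternating
  counts <- array(alt, c(20, 1, 1))
  cs <- structure(list(year = 2001:2020, counts = counts, season = "annual",
                       lat = 35, lon = 240), class = "count_series")
  expect_equal(interannual_sd(cs)[1, 1], sqrt(25 * 20 / 19))  # 5.13
  expect_equal(round(interannual_sd(cs)[1, 1], 2), 5.13)
  const <- cs; const$counts[] <- 12
  expect_equal(interannual_sd(const)[1, 1], 0)
  set.seed(24)
  counts2 <- array(rpois(40, 20), c(10, 2, 2))
  cs2 <- structure(list(year = 2001:2010, counts = counts2,
                        season = "annual", lat = c(35, 40),
                        lon = c(240, 245)), class = "count_series")
  got <- interannual_sd(cs2)
  for (i in 1:2) for (j in 1:2)
    expect_equal(got[i, j], sd(counts2[, i, j]))
})

test_that("ensemble statistics average members and count agreement", {
  yrs <- 2001:2020
  mk <- function(acc) data.frame(
    year = yrs, value = 50 + acc / 19 * (yrs - 2001))
  members <- list(mk(-12), mk(-11), mk(-3))
  es <- ensemble_statistics(members, threshold = 10)
  expect_equal(es$agreement, 2L)
  expect_equal(es$accumulated, c(-12, -11, -3), tolerance = 1e-9)
  expect_equal(es$mean_series$value,
               (members[[1]]$value + members[[2]]$value +
                  members[[3]]$value) / 3)
  # permutation invariance of the agreement count
  es2 <- ensemble_statistics(members[c(3, 1, 2)], threshold = 10)
  expect_equal(es2$agreement, es$agreement)
  # identical members: mean equals the member, agreement all-or-none
  es3 <- ensemble_statistics(list(mk(-5), mk(-5), mk(-5)), threshold = 4)
  expect_equal(es3$mean_series$value, mk(-5)$value)
  expect_equal(es3$agreement, 3L)
  expect_equal(ensemble_statistics(list(mk(-5), mk(-5), mk(-5)),
                                   threshold = 6)$agreement, 0L)
  expect_error(ensemble_statistics(list(mk(1),
                                        data.frame(year = 2002:2021,
                                                   value = 1:20))),
               "ragged")
})
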