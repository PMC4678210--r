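test_that("piecewise generator: determinism, noiseless limit, spec validation", {
  a <- generate_piecewise_series(30, levels = c(10, 4), changepoints = 15,
                                 sigma = 2, seed = 401)
  b <- generate_piecewise_series(30, levels = c(10, 4), changepoints = 15,
                                 sigma = 2, seed = 401)
  expect_identical(a$values, b$values)

  noiseless <- generate_piecewise_series(20, levels = c(1, 5), changepoints = 10,
                                         sigma = 0)
  expect_equal(noiseless$values, rep(c(1, 5), each = 10))

  withslope <- generate_piecewise_series(10, levels = 2, slopes = 0.5, sigma = 0)
  expect_equal(withslope$values, 2 + 0.5 * (0:9))

  # heavy-tailed contamination keeps the nominal spread
  st <- generate_piecewise_series(4000, levels = 0, sigma = 2,
                                  noise = "student", t_df = 5, seed = 402,
                                  start_year = 1L)
  expect_equal(sd(st$values), 2, tolerance = 0.1)
  expect_error(generate_piecewise_series(10, levels = 1, sigma = 1,
                                         noise = "student", t_df = 2), "t_df")

  expect_error(generate_piecewise_series(10, levels = c(1, 2), changepoints = 12,
                                         sigma = 1), "changepoints")
  expect_error(generate_piecewise_series(10, levels = c(1, 2), sigma = 1),
               "one entry per segment")
  expect_error(generate_piecewise_series(10, levels = 1, sigma = -1), "sigma")
})

test_that("generated segments match their specified mean and spread", {
  set.seed(411)
  reps <- 10000
  seg1 <- matrix(NA_real_, reps, 4)
  seg2 <- matrix(NA_real_, reps, 4)
  for (r in 1:reps) {
    ys <- generate_piecewise_series(8, levels = c(10, 20), changepoints = 4,
                                    sigma = 3)
    seg1[r, ] <- ys$values[1:4]
    seg2[r, ] <- ys$values[5:8]
  }
  expect_equal(mean(seg1), 10, tolerance = 0.02)
  expect_equal(mean(seg2), 20, tolerance = 0.02)
  expect_equal(sd(seg1), 3, tolerance = 0.02)
  expect_equal(sd(seg2), 3, tolerance = 0.02)
})

test_that("generated series survive the CSV round trip", {
  ys <- generate_piecewise_series(25, levels = c(100, 92), changepoints = 12,
                                  sigma = 6, missing_rate = 0.1, seed = 421)
  p <- withr::local_tempfile(fileext = ".csv")
  write_year_series(ys, p)
  back <- read_year_series(p)
  expect_equal(back$years, ys$years)
  expect_equal(back$values, ys$values, tolerance = 1e-12)
})

test_that("noiseless daily construction reproduces the annual targets exactly", {
  periods <- period_preset("europe")
  target <- year_series(1990:1994, c(7.5, 8.0, 8.8, 8.2, 9.0), label = "HA")
  daily <- generate_daily_temperatures(list(ha = target), periods,
                                       daily_sd = 0, seed = 431)
  got <- suppressWarnings(aggregate_period_mean(daily, periods$ha))
  expect_equal(got$values[match(target$years, got$years)], target$values,
               tolerance = 1e-10)
})

test_that("a stepped HA target is recovered through the daily pipeline", {
  periods <- period_preset("europe")
  set.seed(441)
  hits <- 0
  reps <- 200
  for (r in 1:reps) {
    target <- generate_piecewise_series(40, levels = c(7.5, 8.8),
                                        changepoints = 20, sigma = 0,
                                        start_year = 1974, label = "HA")
    daily <- generate_daily_temperatures(list(ha = target), periods,
                                         daily_sd = 2)
    ha <- aggregate_period_mean(daily, periods$ha)
    fit <- optimal_segmentation(ha, 2, "constant")
    if (abs(fit$cp_years - 1994) <= 1) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.9)
})

test_that("short interpolated gaps barely perturb the period means", {
  periods <- period_preset("europe")
  target <- year_series(2000, 8.2, label = "HA")
  daily <- generate_daily_temperatures(list(ha = target), periods,
                                       daily_sd = 2, seed = 451)
  truth <- suppressWarnings(aggregate_period_mean(daily, periods$ha))
  set.seed(452)
  for (gap in 1:3) {
    drop <- sample(seq(10, nrow(daily) - 10), 1)
    holed <- daily[-(drop:(drop + gap - 1)), c("date", "tmin", "tmax")]
    holed <- daily_temperatures(holed$date, holed$tmin, holed$tmax)
    filled <- interpolate_missing_daily(holed)
    got <- suppressWarnings(aggregate_period_mean(filled, periods$ha))
    expect_lt(abs(got$values - truth$values), 0.05)
  }
})

test_that("scenario bundles are pure functions of name and seed", {
  a <- generate_scenario_bundle("european", 461)
  b <- generate_scenario_bundle("european", 461)
  expect_identical(a$flowering$values, b$flowering$values)
  expect_identical(a$daily$tmean, b$daily$tmean)
  expect_identical(a$durations, b$durations)
  expect_error(generate_scenario_bundle("alpine", 1), "arg")
})

test_that("scenario bundles carry the intended couplings and regimes", {
  # Brazilian: stationary flowering positively coupled to the CA mean
  bz <- generate_scenario_bundle("brazilian", 471)
  ct <- correlate_flowering_temperature(bz$flowering, bz$ca_target)
  expect_gt(ct$r, 0)
  expect_equal(ct$class, "**")

  # European: flowering advances, HA warms concomitantly, negative coupling
  eu <- generate_scenario_bundle("european", 472)
  expect_equal(eu$truth$flowering_amplitude, -8)
  expect_equal(eu$truth$ha_cp_year, eu$truth$flowering_cp_year)
  ct <- correlate_flowering_temperature(eu$flowering, eu$ha_target)
  expect_lt(ct$r, 0)

  # Mediterranean: HA steps up but the flowering generator transmits only
  # anomalies, so its mean function is flat
  md <- scenario_spec("mediterranean")
  expect_equal(md$flowering$amplitude, 0)
  expect_equal(diff(md$ha$levels), 1.31, tolerance = 1e-12)
})
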