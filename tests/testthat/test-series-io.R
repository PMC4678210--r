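test_that("annual series CSV parsing handles values, missing cells and errors", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("year,value", "1987,105", "1988,96", "1989,94"), p)
  ys <- read_year_series(p, label = "demo")
  expect_s3_class(ys, "year_series")
  expect_length(ys, 3)
  expect_equal(ys$years, 1987:1989)
  expect_equal(ys$values, c(105, 96, 94))

  writeLines(c("year,value", "1989,94", "1990,", "1991,101"), p)
  ys <- read_year_series(p)
  expect_true(is.na(ys$values[ys$years == 1990]))
  expect_equal(n_obs(ys), 2)

  writeLines(c("year,value", "1990,94", "1990,95"), p)
  expect_error(read_year_series(p), "duplicate year")

  writeLines(c("year,value", "1990,94", "1991,oops"), p)
  expect_error(read_year_series(p), "row 2.*oops")
})

test_that("annual series survive a CSV round trip, missing values included", {
  ys <- year_series(2000:2009, c(1.5, NA, 3, 4.25, NA, 6, 7, 8, 9, 10.125),
                    label = "rt")
  p <- withr::local_tempfile(fileext = ".csv")
  write_year_series(ys, p)
  back <- read_year_series(p, label = "rt")
  expect_equal(back$years, ys$years)
  expect_equal(back$values, ys$values)
})

test_that("year_series enforces its invariants", {
  expect_error(year_series(c(2000, 2000), c(1, 2)), "strictly increasing")
  expect_error(year_series(c(2001, 2000), c(1, 2)), "strictly increasing")
  expect_error(year_series(2000:2001, c(1, Inf)), "finite")
  expect_error(year_series(2000:2002, c(1, 2)), "same length")
})

test_that("daily interpolation fills interior gaps and refuses bad ones", {
  d <- seq(as.Date("2000-01-01"), as.Date("2000-01-05"), by = "day")
  rec <- daily_temperatures(d[-2], tmin = c(8, 10, 9, 8), tmax = c(12, 14, 15, 12))
  out <- interpolate_missing_daily(rec)
  expect_equal(nrow(out), 5)
  expect_equal(out$tmean[2], (10 + 12) / 2)  # midpoint of neighbouring tmeans
  expect_equal(out$tmin[2], 9)
  expect_equal(out$tmean, (out$tmin + out$tmax) / 2)

  # no gaps: identity
  rec2 <- daily_temperatures(d, tmin = 1:5, tmax = 11:15)
  expect_equal(interpolate_missing_daily(rec2)[, c("tmin", "tmax", "tmean")],
               rec2[, c("tmin", "tmax", "tmean")])

  # 15-day interior gap exceeds the default cap
  d3 <- seq(as.Date("2000-01-01"), as.Date("2000-01-20"), by = "day")
  rec3 <- daily_temperatures(d3[c(1, 2, 18, 19, 20)],
                             tmin = rep(5, 5), tmax = rep(15, 5))
  expect_error(interpolate_missing_daily(rec3), "exceeds max_gap")

  # gap at the boundary cannot be interpolated
  rec4 <- daily_temperatures(d, tmin = c(NA, 2, 3, 4, 5), tmax = c(NA, 12, 13, 14, 15))
  expect_error(interpolate_missing_daily(rec4), "boundary")
})

test_that("period aggregation: constants, ramps, labelling and order invariance", {
  ca <- period_definition("CA", 10, 1, 1)  # Oct -- Jan
  d <- seq(as.Date("1987-10-01"), as.Date("1988-01-31"), by = "day")
  rec <- daily_temperatures(d, tmin = rep(4, length(d)), tmax = rep(12, length(d)))
  ys <- suppressWarnings(aggregate_period_mean(rec, ca))
  expect_equal(ys$years, 1988)        # cross-year window labelled by its end year
  expect_equal(ys$values, 8.0)

  # ramp 0..(n-1) over the window -> mean (n-1)/2
  n <- length(d)
  rec2 <- daily_temperatures(d, tmin = 0:(n - 1) - 1, tmax = 0:(n - 1) + 1)
  expect_equal(suppressWarnings(aggregate_period_mean(rec2, ca))$values, (n - 1) / 2)

  # order of input records is irrelevant
  shuf <- rec2[sample(nrow(rec2)), ]
  expect_equal(suppressWarnings(aggregate_period_mean(shuf, ca))$values, (n - 1) / 2)
})

test_that("NH chill window labelling holds across consecutive years", {
  ca <- period_definition("CA", 10, 1, 1)
  d <- seq(as.Date("1990-10-01"), as.Date("1992-01-31"), by = "day")
  jan91 <- format(d, "%Y-%m") %in% c("1990-10", "1990-11", "1990-12", "1991-01")
  vals <- ifelse(jan91, 5, 7)
  rec <- daily_temperatures(d, vals - 4, vals + 4)
  ys <- suppressWarnings(aggregate_period_mean(rec, ca))
  expect_equal(ys$years, c(1991, 1992))
  expect_equal(ys$values, c(5, 7))
})

test_that("a temperature step inside the HA window matches a daily-sum oracle", {
  ha <- period_definition("HA", 2, 1, 4)  # Feb -- Apr
  d <- seq(as.Date("1999-12-01"), as.Date("2000-05-15"), by = "day")
  base <- 6 + 0.01 * seq_along(d)
  step <- ifelse(d >= as.Date("2000-03-10"), 1.3, 0)  # warming step mid-window
  rec <- daily_temperatures(d, base + step - 3, base + step + 3)
  ys <- suppressWarnings(aggregate_period_mean(rec, ha))
  inwin <- d >= as.Date("2000-02-01") & d <= as.Date("2000-04-30")
  oracle <- sum(base[inwin] + step[inwin]) / sum(inwin)  # brute-force daily sum
  expect_equal(ys$values[ys$years == 2000], oracle, tolerance = 1e-12)
})

test_that("mid-April period end is inclusive of the 15th", {
  ha <- period_preset("morocco")$ha
  w <- phenoseg:::period_window(ha, 2001L)
  expect_equal(w$start, as.Date("2001-03-01"))
  expect_equal(w$end, as.Date("2001-04-15"))
})

test_that("incomplete period coverage yields a missing year with a warning", {
  ca <- period_definition("CA", 10, 1, 1)
  d <- seq(as.Date("1987-10-01"), as.Date("1988-01-31"), by = "day")
  vals <- rep(8, length(d)); vals[20] <- NA
  rec <- daily_temperatures(d, vals - 4, vals + 4)
  expect_warning(ys <- aggregate_period_mean(rec, ca), "incomplete")
  expect_true(is.na(ys$values[ys$years == 1988]))
})

test_that("period definitions can be read from YAML config", {
  p <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("ca:", "  start_month: 10", "  end_month: 1",
               "ha:", "  start_month: 3", "  end_month: 4", "  end_day: 15"), p)
  cfg <- read_period_config(p)
  expect_named(cfg, c("ca", "ha"))
  expect_equal(cfg$ha$end_day, 15L)
  expect_equal(phenoseg:::period_window(cfg$ca, 2000L)$start, as.Date("1999-10-01"))
})
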