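test_that("single-segment fits: means, exact lines and a grid-search oracle", {
  f <- fit_segment(c(3, 5, 7), 1, 3, "constant")
  expect_equal(f$alpha, 5)
  expect_equal(f$beta, 0)
  expect_equal(f$rss, 8)

  # exact line on t = 0, 1, 2
  f <- fit_segment(c(1, 2, 3), 1, 3, "linear")
  expect_equal(f$beta, 1, tolerance = 1e-12)
  expect_equal(f$rss, 0, tolerance = 1e-12)

  # random 10-point segment against a coarse-to-fine grid search over (a, b)
  set.seed(11)
  x <- rnorm(10, 5, 2)
  t <- 0:9
  f <- fit_segment(x, 1, 10, "linear")
  a_grid <- seq(f$alpha - 1, f$alpha + 1, length.out = 41)
  b_grid <- seq(f$beta - 1, f$beta + 1, length.out = 41)
  for (pass in 1:8) {
    rss_grid <- outer(a_grid, b_grid,
                      Vectorize(function(a, b) sum((x - a - b * t)^2)))
    i <- which(rss_grid == min(rss_grid), arr.ind = TRUE)[1, ]
    wa <- diff(range(a_grid)) / 4; wb <- diff(range(b_grid)) / 4
    a_grid <- seq(a_grid[i[1]] - wa, a_grid[i[1]] + wa, length.out = 41)
    b_grid <- seq(b_grid[i[2]] - wb, b_grid[i[2]] + wb, length.out = 41)
  }
  expect_equal(f$rss, min(rss_grid), tolerance = 1e-6)

  expect_error(fit_segment(c(1, NA), 1, 2, "linear"), "too few")
})

test_that("dynamic programming finds the exact optimum (enumeration oracle)", {
  set.seed(21)
  for (rep in 1:12) {
    T <- sample(12:30, 1)
    x <- rnorm(T) + rep(c(0, sample(c(-2, 0, 2), 1)), length.out = T)
    t <- 1974 + 0:(T - 1)
    ys <- year_series(t, x)
    for (family in c("constant", "linear")) {
      for (J in 2:3) {
        ml <- phenoseg:::default_min_seg_len(family)
        fit <- optimal_segmentation(ys, J, family)
        oracle <- best_seg_oracle(x, t, J, family, ml)
        expect_equal(fit$ends, as.integer(oracle))
        expect_equal(fit$rss_total, rss_ends_oracle(x, t, oracle, family),
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("a clean step is segmented exactly and J = 1 linear equals lm", {
  ys <- year_series(1981:2000, c(rep(0, 10), rep(5, 10)))
  fit <- optimal_segmentation(ys, 2, "constant")
  expect_equal(fit$changepoints, 10L)
  expect_equal(fit$cp_years, 1991L)
  expect_equal(fit$amplitudes, 5)

  set.seed(31)
  ys <- year_series(1980:2009, rnorm(30, 100, 5) - 0.3 * (0:29))
  fit <- optimal_segmentation(ys, 1, "linear")
  lmfit <- lm(ys$values ~ ys$years)
  expect_equal(fit$alpha[1], unname(coef(lmfit)[1]), tolerance = 1e-10)
  expect_equal(fit$beta[1], unname(coef(lmfit)[2]), tolerance = 1e-10)
  expect_equal(fit$rss_total, sum(residuals(lmfit)^2), tolerance = 1e-10)
})

test_that("optimal RSS is non-increasing in J and infeasible J errors", {
  set.seed(41)
  ys <- year_series(1974:2003, rnorm(30, 50, 4))
  rss <- vapply(1:4, function(J) optimal_segmentation(ys, J, "constant")$rss_total,
                numeric(1))
  expect_true(all(diff(rss) <= 1e-9))
  expect_error(optimal_segmentation(ys, 20, "constant"), "infeasible")
})

test_that("segmentations are equivariant under shift and scale", {
  set.seed(51)
  ys <- step_series(30, 14, c(10, 6), 2, seed = 51)
  base <- optimal_segmentation(ys, 2, "constant")
  shifted <- year_series(ys$years, ys$values + 100)
  scaled <- year_series(ys$years, ys$values * 3)
  fs <- optimal_segmentation(shifted, 2, "constant")
  fc <- optimal_segmentation(scaled, 2, "constant")
  expect_equal(fs$ends, base$ends)
  expect_equal(fs$alpha, base$alpha + 100)
  expect_equal(fs$amplitudes, base$amplitudes)
  expect_equal(fc$ends, base$ends)
  expect_equal(fc$amplitudes, base$amplitudes * 3)
  expect_equal(fc$sigma2, base$sigma2 * 9, tolerance = 1e-10)
})

test_that("log-likelihood: closed form, optimality and density-product oracle", {
  # n = 4 with RSS = 4 gives sigma2 = 1, logL = -2 (log 2pi + 1)
  ys <- year_series(2001:2004, c(-1, 1, -1, 1))
  expect_equal(log_likelihood(ys, 4L, "constant"),
               -2 * (log(2 * pi) + 1), tolerance = 1e-12)

  set.seed(61)
  ys <- year_series(1990:2004, rnorm(15, 20, 3))
  x <- ys$values; t <- as.numeric(ys$years)
  opt <- optimal_segmentation(ys, 2, "constant", min_seg_len = 1)
  ll_opt <- log_likelihood(ys, opt, "constant")
  for (tau in 1:14) {
    ll <- log_likelihood(ys, c(tau, 15L), "constant")
    expect_lte(ll, ll_opt + 1e-10)
    expect_equal(ll, loglik_oracle(x, t, c(tau, 15), "constant"),
                 tolerance = 1e-10)
  }

  # degenerate zero-RSS fit signals a condition instead of returning Inf
  flat <- year_series(2001:2010, rep(3, 10))
  expect_error(log_likelihood(flat, 10L, "constant"),
               class = "phenoseg_degenerate")
})

test_that("missing observations are skipped, not interpolated", {
  set.seed(71)
  x <- c(rnorm(12, 0), rnorm(12, 4))
  x[c(3, 15, 20)] <- NA
  t <- 1980 + 0:23
  ys <- year_series(t, x)
  fit <- optimal_segmentation(ys, 2, "constant")
  oracle <- best_seg_oracle(x, t, 2, "constant", 2)
  expect_equal(fit$ends, as.integer(oracle))
  expect_equal(fit$n_obs, 21)
  # segment means ignore the NAs
  s1 <- x[1:fit$ends[1]]
  expect_equal(fit$alpha[1], mean(s1, na.rm = TRUE))
})
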