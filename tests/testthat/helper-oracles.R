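# Independent oracles used to validate the dynamic-programming and posterior
# machinery on small problems: exhaustive enumeration of segmentations,
# per-segment least squares through stats::lm, and per-point Gaussian density
# products. These deliberately avoid the package's prefix-sum code paths.

# All segmentations of 1..T into J segments with raw length >= min_len,
# as a matrix of cumulative end indices.
enum_ends_oracle <- function(T, J, min_len = 1) {
  if (J == 1) return(matrix(T, 1, 1))
  cuts <- utils::combn(T - 1, J - 1)
  keep <- apply(cuts, 2, function(cp) all(diff(c(0, cp, T)) >= min_len))
  m <- t(cuts[, keep, drop = FALSE])
  cbind(m, T, deparse.level = 0)
}

# RSS of one segment via stats::lm (or plain mean), skipping NAs.
rss_seg_oracle <- function(x, t, i, j, family) {
  xs <- x[i:j]; ts <- t[i:j]
  ok <- !is.na(xs)
  xs <- xs[ok]; ts <- ts[ok]
  if (family == "constant") {
    sum((xs - mean(xs))^2)
  } else {
    sum(stats::lm(xs ~ ts)$residuals^2)
  }
}

rss_ends_oracle <- function(x, t, ends, family) {
  starts <- c(1, ends[-length(ends)] + 1)
  sum(mapply(function(i, j) rss_seg_oracle(x, t, i, j, family), starts, ends))
}

# Exhaustive-search optimal segmentation (earliest ends on ties).
best_seg_oracle <- function(x, t, J, family, min_len) {
  ends <- enum_ends_oracle(length(x), J, min_len)
  rss <- apply(ends, 1, function(e) rss_ends_oracle(x, t, e, family))
  ends[which.min(rss), ]
}

# Log-likelihood of a segmentation as a per-point Gaussian density product:
# fitted values from per-segment lm fits, pooled ML variance.
loglik_oracle <- function(x, t, ends, family) {
  starts <- c(1, ends[-length(ends)] + 1)
  fitted <- rep(NA_real_, length(x))
  for (k in seq_along(ends)) {
    idx <- starts[k]:ends[k]
    ok <- idx[!is.na(x[idx])]
    if (family == "constant") {
      fitted[ok] <- mean(x[ok])
    } else {
      fm <- stats::lm(x[ok] ~ t[ok])
      fitted[ok] <- stats::fitted(fm)
    }
  }
  ok <- !is.na(x)
  rss <- sum((x[ok] - fitted[ok])^2)
  s2 <- rss / sum(ok)
  sum(stats::dnorm(x[ok], fitted[ok], sqrt(s2), log = TRUE))
}

# A seeded Gaussian step series as a year_series.
step_series <- function(T, cp, levels, sigma, seed, start_year = 1974) {
  set.seed(seed)
  vals <- c(rnorm(cp, levels[1], sigma), rnorm(T - cp, levels[2], sigma))
  year_series(start_year + 0:(T - 1), vals)
}
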