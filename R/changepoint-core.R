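# Homoscedastic Gaussian multiple change-point models.
#
# A segmentation of a series of length T into J segments is encoded by the
# vector `ends` of cumulative segment end indices (ends[J] == T); the J - 1
# change points are ends[1..J-1], and segment j covers indices
# (ends[j-1] + 1):ends[j]. Within each segment the mean is either constant
# (family "constant") or linear in time (family "linear"); the variance is
# pooled across segments (homoscedastic). Missing observations are skipped in
# all sums, never interpolated.

FAMILIES <- c("constant", "linear")

# Minimum raw segment length used by the optimisation when none is supplied.
default_min_seg_len <- function(family) if (family == "constant") 2L else 3L

# Minimum non-missing count for a segment fit to be defined.
min_obs_for_fit <- function(family) if (family == "constant") 1L else 2L

as_series_values <- function(series) {
  if (inherits(series, "year_series")) {
    list(x = series$values, t = as.numeric(series$years), years = series$years,
         label = series$label)
  } else {
    x <- as.numeric(series)
    list(x = x, t = seq_along(x) - 1, years = seq_along(x), label = "")
  }
}

# Prefix-sum machinery giving O(1) per-segment RSS and coefficients.
make_seg_stats <- function(x, t) {
  obs <- !is.na(x)
  x0 <- ifelse(obs, x, 0)
  t0 <- ifelse(obs, t, 0)
  list(
    n  = c(0, cumsum(as.numeric(obs))),
    sx = c(0, cumsum(x0)),
    sx2 = c(0, cumsum(x0^2)),
    st = c(0, cumsum(t0)),
    st2 = c(0, cumsum(t0^2)),
    stx = c(0, cumsum(t0 * x0))
  )
}

# Least-squares fit of one segment [i, j] (1-based, inclusive).
# Returns list(alpha, beta, rss, n, stt) or NULL if infeasible.
seg_fit_ij <- function(S, i, j, family) {
  n <- S$n[j + 1] - S$n[i]
  if (n < min_obs_for_fit(family)) return(NULL)
  sx <- S$sx[j + 1] - S$sx[i]
  sx2 <- S$sx2[j + 1] - S$sx2[i]
  sxx <- sx2 - sx^2 / n
  if (family == "constant") {
    return(list(alpha = sx / n, beta = 0, rss = max(sxx, 0), n = n, stt = NA_real_))
  }
  st <- S$st[j + 1] - S$st[i]
  st2 <- S$st2[j + 1] - S$st2[i]
  stx <- S$stx[j + 1] - S$stx[i]
  stt <- st2 - st^2 / n
  if (stt <= 0) return(NULL)  # would need >= 2 distinct time points
  sxt <- stx - st * sx / n
  beta <- sxt / stt
  alpha <- (sx - beta * st) / n
  list(alpha = alpha, beta = beta, rss = max(sxx - sxt^2 / stt, 0), n = n, stt = stt)
}

#' Fit a single segment
#'
#' Least-squares fit of one segment of a series under the constant or linear
#' family. For the constant family the intercept is the segment mean; for the
#' linear family an ordinary least-squares line is fitted on (time, value)
#' pairs within the segment. Missing observations are skipped with counts
#' adjusted.
#'
#' @param series A [year_series()] or numeric vector (for plain vectors the
#'   time axis is `0:(T-1)`).
#' @param start,end First and last index of the segment (1-based, inclusive).
#' @param family `"constant"` or `"linear"`.
#' @return A list with `alpha` (intercept), `beta` (slope, 0 for the constant
#'   family), `rss` (residual sum of squares) and `n` (non-missing count).
#' @examples
#' fit_segment(c(3, 5, 7), 1, 3, "constant")   # alpha 5, rss 8
#' @export
fit_segment <- function(series, start, end, family = c("constant", "linear")) {
  family <- match.arg(family)
  sv <- as_series_values(series)
  T <- length(sv$x)
  stopifnot(start >= 1, end <= T, start <= end)
  S <- make_seg_stats(sv$x, sv$t)
  f <- seg_fit_ij(S, as.integer(start), as.integer(end), family)
  if (is.null(f)) {
    stop(sprintf("segment [%d, %d] has too few non-missing points for the %s family",
                 start, end, family), call. = FALSE)
  }
  f[c("alpha", "beta", "rss", "n")]
}

# Segment cost matrix: C[i, j] = minimal RSS of segment i..j, Inf if the
# segment is infeasible (too short in raw length or in non-missing count).
seg_cost_matrix <- function(x, t, family, min_seg_len) {
  T <- length(x)
  S <- make_seg_stats(x, t)
  C <- matrix(Inf, T, T)
  min_n <- min_obs_for_fit(family)
  for (i in 1:T) {
    jmin <- i + min_seg_len - 1L
    if (jmin > T) break
    js <- jmin:T
    n <- S$n[js + 1] - S$n[i]
    sx <- S$sx[js + 1] - S$sx[i]
    sx2 <- S$sx2[js + 1] - S$sx2[i]
    if (family == "constant") {
      rss <- ifelse(n >= min_n, pmax(sx2 - sx^2 / pmax(n, 1), 0), Inf)
    } else {
      st <- S$st[js + 1] - S$st[i]
      st2 <- S$st2[js + 1] - S$st2[i]
      stx <- S$stx[js + 1] - S$stx[i]
      stt <- st2 - st^2 / pmax(n, 1)
      sxt <- stx - st * sx / pmax(n, 1)
      rss <- ifelse(n >= min_n & stt > 0,
                    pmax(sx2 - sx^2 / pmax(n, 1) - sxt^2 / ifelse(stt > 0, stt, 1), 0),
                    Inf)
    }
    C[i, js] <- rss
  }
  C
}

# Gaussian log-likelihood of a segmentation from its total RSS under the
# pooled maximum-likelihood variance sigma2 = rss / n_obs:
# logL = -(n/2) (log(2 pi sigma2) + 1). Returns NA for a degenerate
# (zero-RSS) fit; callers decide how to signal it.
ll_from_rss <- function(rss, n_obs) {
  if (!is.finite(rss) || rss <= 0) return(NA_real_)
  -(n_obs / 2) * (log(2 * pi * rss / n_obs) + 1)
}

build_segmentation_fit <- function(series, ends, family, min_seg_len = NULL) {
  sv <- as_series_values(series)
  T <- length(sv$x)
  ends <- as.integer(ends)
  J <- length(ends)
  if (ends[J] != T || any(diff(c(0L, ends)) < 1L) || is.unsorted(ends, strictly = TRUE)) {
    stop("invalid segmentation: ends must be strictly increasing and finish at T",
         call. = FALSE)
  }
  S <- make_seg_stats(sv$x, sv$t)
  starts <- c(1L, ends[-J] + 1L)
  alpha <- beta <- rss <- n_seg <- stt <- numeric(J)
  seg_mean <- numeric(J)
  for (j in seq_len(J)) {
    f <- seg_fit_ij(S, starts[j], ends[j], family)
    if (is.null(f)) {
      stop(sprintf("segment %d ([%d, %d]) has too few non-missing points for the %s family",
                   j, starts[j], ends[j], family), call. = FALSE)
    }
    alpha[j] <- f$alpha; beta[j] <- f$beta; rss[j] <- f$rss
    n_seg[j] <- f$n; stt[j] <- f$stt
    # fitted segment mean = mean of fitted values over the segment's
    # non-missing time points (equals alpha for the constant family)
    tbar <- (S$st[ends[j] + 1] - S$st[starts[j]]) / f$n
    seg_mean[j] <- f$alpha + f$beta * tbar
  }
  n_total <- sum(n_seg)
  rss_total <- sum(rss)
  sigma2 <- rss_total / n_total
  ll <- ll_from_rss(rss_total, n_total)
  structure(list(
    family = family, J = J, ends = ends, changepoints = ends[-J],
    cp_years = if (J > 1) sv$years[ends[-J] + 1L] else integer(0),
    seg_lengths = diff(c(0L, ends)),
    alpha = alpha, beta = beta, seg_means = seg_mean,
    amplitudes = if (J > 1) diff(seg_mean) else numeric(0),
    rss = rss, rss_total = rss_total, n_seg = n_seg, n_obs = n_total,
    stt = stt, sigma2 = sigma2, sd = sqrt(sigma2), loglik = ll,
    degenerate = is.na(ll), T = T, years = sv$years, label = sv$label,
    min_seg_len = if (is.null(min_seg_len)) NA_integer_ else as.integer(min_seg_len)
  ), class = "segmentation_fit")
}

#' @export
print.segmentation_fit <- function(x, ...) {
  cat(sprintf("<segmentation_fit> %s family, J = %d, n = %d\n",
              x$family, x$J, x$n_obs))
  if (x$J > 1) {
    cat(sprintf("  change points (year of first obs of new segment): %s\n",
                paste(x$cp_years, collapse = ", ")))
    cat(sprintf("  amplitudes: %s\n",
                paste(sprintf("%.2f", x$amplitudes), collapse = ", ")))
  }
  cat(sprintf("  sigma = %.3f, logL = %s%s\n", x$sd,
              if (x$degenerate) "degenerate (zero RSS)" else sprintf("%.3f", x$loglik),
              ""))
  invisible(x)
}

#' Optimal segmentation into J segments by dynamic programming
#'
#' Finds the segmentation into exactly `J` segments minimising the total
#' residual sum of squares over all admissible segmentations, equivalently
#' maximising the homoscedastic Gaussian likelihood. Ties are broken toward
#' the earliest change points so results are deterministic. With `J = 1` and
#' the linear family this reduces to simple linear regression on the whole
#' series.
#'
#' @param series A [year_series()] or numeric vector.
#' @param J Number of segments (>= 1).
#' @inheritParams fit_segment
#' @param min_seg_len Minimum raw segment length; defaults to 2 for the
#'   constant family and 3 for the linear family. Each segment must in
#'   addition contain at least 1 (constant) or 2 (linear) non-missing points.
#' @return A `segmentation_fit` object with per-segment intercepts `alpha`,
#'   slopes `beta`, fitted segment means, change-point amplitudes
#'   (post-segment mean minus pre-segment mean, so flowering advances are
#'   negative), pooled variance `sigma2` and log-likelihood.
#' @export
optimal_segmentation <- function(series, J, family = c("constant", "linear"),
                                 min_seg_len = NULL) {
  family <- match.arg(family)
  if (is.null(min_seg_len)) min_seg_len <- default_min_seg_len(family)
  min_seg_len <- max(1L, as.integer(min_seg_len))
  sv <- as_series_values(series)
  T <- length(sv$x)
  J <- as.integer(J)
  if (J < 1) stop("J must be >= 1", call. = FALSE)
  if (J * min_seg_len > T) {
    stop(sprintf("segmentation into %d segments of length >= %d is infeasible for T = %d",
                 J, min_seg_len, T), call. = FALSE)
  }
  C <- seg_cost_matrix(sv$x, sv$t, family, min_seg_len)
  if (J == 1) {
    if (!is.finite(C[1, T])) stop("whole-series fit is infeasible", call. = FALSE)
    return(build_segmentation_fit(series, T, family, min_seg_len))
  }
  # D[k, j]: min cost of segmenting 1..j into k segments; B[k, j]: argmin end
  # of segment k-1 (earliest on ties).
  D <- matrix(Inf, J, T)
  B <- matrix(NA_integer_, J, T)
  D[1, ] <- C[1, ]
  for (k in 2:J) {
    for (j in (k * min_seg_len):T) {
      best <- Inf; bi <- NA_integer_
      for (i in ((k - 1) * min_seg_len):(j - min_seg_len)) {
        v <- D[k - 1, i] + C[i + 1, j]
        if (v < best) { best <- v; bi <- i }
      }
      D[k, j] <- best; B[k, j] <- bi
    }
  }
  if (!is.finite(D[J, T])) {
    stop(sprintf("no feasible segmentation into %d segments (missing data too sparse?)", J),
         call. = FALSE)
  }
  ends <- integer(J); ends[J] <- T
  for (k in J:2) ends[k - 1] <- B[k, ends[k]]
  build_segmentation_fit(series, ends, family, min_seg_len)
}

#' Refit a given segmentation
#'
#' Fits the within-segment parameters and pooled variance for a fixed
#' segmentation (no optimisation of the change points).
#'
#' @inheritParams optimal_segmentation
#' @param ends Integer vector of cumulative segment end indices, finishing at
#'   the series length.
#' @return A `segmentation_fit`.
#' @export
refit_segmentation <- function(series, ends, family = c("constant", "linear")) {
  family <- match.arg(family)
  build_segmentation_fit(series, ends, family)
}

#' Log-likelihood of a segmentation
#'
#' Gaussian log-likelihood of a series under a segmentation, with
#' segment-specific means and the pooled maximum-likelihood variance
#' `sigma2 = RSS / n`; in closed form `-(n/2) (log(2 pi sigma2) + 1)`. A
#' zero-RSS (perfect) fit has no finite maximised Gaussian likelihood and is
#' signalled as a condition of class `phenoseg_degenerate` rather than
#' returned as infinity.
#'
#' @inheritParams refit_segmentation
#' @param segmentation A `segmentation_fit` or an integer vector of segment
#'   end indices.
#' @return The log-likelihood (a scalar).
#' @export
log_likelihood <- function(series, segmentation, family = c("constant", "linear")) {
  family <- match.arg(family)
  fit <- if (inherits(segmentation, "segmentation_fit")) {
    segmentation
  } else {
    build_segmentation_fit(series, segmentation, family)
  }
  if (fit$degenerate) {
    stop(errorCondition(
      "degenerate segmentation: zero residual sum of squares (likelihood unbounded)",
      class = c("phenoseg_degenerate", "error", "condition")
    ))
  }
  fit$loglik
}
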