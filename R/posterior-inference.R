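# Posterior assessment of the segmentation assumption. For short series and
# few segments, all segmentations into J segments can be enumerated; each is
# refitted (its own segment means and pooled variance), and likelihood weights
# give the posterior probability of the optimal segmentation and, for J = 2,
# the full change-point posterior distribution.

#' Enumerate all segmentations into J segments
#'
#' All ways of cutting indices `1..T` into `J` ordered non-empty segments with
#' raw length at least `min_len`. For `J = 2` with `min_len = 1` there are
#' `T - 1` segmentations, one per candidate change point.
#'
#' @param T Series length.
#' @param J Number of segments (1 to 3).
#' @param min_len Minimum raw segment length (default 1).
#' @param cap Maximum `T` accepted (guards combinatorial growth; default 100).
#' @return Integer matrix, one row per segmentation, columns the cumulative
#'   segment end indices (last column is `T`).
#' @export
enumerate_segmentations <- function(T, J, min_len = 1, cap = 100) {
  T <- as.integer(T); J <- as.integer(J); min_len <- as.integer(min_len)
  if (T > cap) {
    stop(sprintf("T = %d exceeds the enumeration cap (%d); use optimal_segmentation for point estimates",
                 T, cap), call. = FALSE)
  }
  if (J < 1 || J > 3) stop("enumeration supports J between 1 and 3", call. = FALSE)
  if (J * min_len > T) stop("no segmentation satisfies the minimum length", call. = FALSE)
  if (J == 1) return(matrix(T, 1, 1))
  if (J == 2) {
    e1 <- seq.int(min_len, T - min_len)
    return(cbind(e1, rep.int(T, length(e1)), deparse.level = 0))
  }
  rows <- list()
  for (e1 in seq.int(min_len, T - 2L * min_len)) {
    e2 <- seq.int(e1 + min_len, T - min_len)
    rows[[length(rows) + 1L]] <- cbind(e1, e2, T, deparse.level = 0)
  }
  do.call(rbind, rows)
}

# Log-likelihood of every enumerated segmentation, computed from the segment
# cost matrix (each segmentation refitted with its own theta-hat). Rows whose
# segments are infeasible get -Inf; degenerate (zero-RSS) rows get NA.
enum_logliks <- function(series, ends_mat, family) {
  sv <- as_series_values(series)
  T <- length(sv$x)
  C <- seg_cost_matrix(sv$x, sv$t, family, min_seg_len = 1L)
  n_total <- sum(!is.na(sv$x))
  apply(ends_mat, 1, function(ends) {
    starts <- c(1L, ends[-length(ends)] + 1L)
    rss <- sum(C[cbind(starts, ends)])
    if (!is.finite(rss)) return(-Inf)
    ll_from_rss(rss, n_total)
  })
}

#' Posterior probability of the optimal segmentation
#'
#' Enumerates all segmentations into `J` segments, refits each with its own
#' parameter estimates, and normalises the likelihoods:
#' `P(s* | x; J) = L(s*, x) / sum_s L(s, x)`. The optimal segmentation `s*`
#' is the dynamic-programming optimum under the same minimum segment length,
#' and its posterior probability is the maximum weight. Accumulation is done
#' in the log domain with max-shifting. Degenerate zero-RSS segmentations
#' (whose Gaussian likelihood is unbounded) are excluded with a warning and
#' the weights renormalised.
#'
#' @inheritParams optimal_segmentation
#' @param min_seg_len Minimum raw segment length for both the enumeration and
#'   the optimum (default 1, so that for `J = 2` all `T - 1` candidate change
#'   points are weighed).
#' @param cap Enumeration cap on `T` (default 100).
#' @return An object of class `posterior_summary`: list with `J`, `family`,
#'   `opt_ends`, `opt_cp_years`, `prob_opt`, `n_enumerated`, `n_excluded` and
#'   `log_weights` (normalised log posterior per enumerated segmentation).
#' @export
segmentation_posterior <- function(series, J, family = c("constant", "linear"),
                                   min_seg_len = 1, cap = 100) {
  family <- match.arg(family)
  sv <- as_series_values(series)
  T <- length(sv$x)
  ends_mat <- enumerate_segmentations(T, J, min_len = min_seg_len, cap = cap)
  ll <- enum_logliks(series, ends_mat, family)
  degen <- is.na(ll)
  if (any(degen)) {
    warning(sprintf("%d degenerate segmentation(s) excluded from the posterior",
                    sum(degen)), call. = FALSE)
    ll[degen] <- -Inf
  }
  keep <- is.finite(ll)
  if (!any(keep)) stop("no segmentation with a finite likelihood", call. = FALSE)
  m <- max(ll[keep])
  w <- exp(ll - m)
  w[!keep] <- 0
  norm <- sum(w)
  post <- w / norm
  opt <- optimal_segmentation(series, J, family, min_seg_len = min_seg_len)
  i_opt <- which(apply(ends_mat, 1, function(e) all(e == opt$ends)))[1]
  if (is.na(i_opt)) stop("internal error: optimum not among enumerated segmentations")
  # mode consistency: the DP optimum maximises the likelihood, hence the
  # weight (unless it was itself excluded as degenerate)
  if (!degen[i_opt]) stopifnot(post[i_opt] >= max(post) - 1e-12)
  structure(list(
    J = J, family = family, T = T,
    opt_ends = opt$ends,
    opt_cp_years = opt$cp_years,
    prob_opt = post[i_opt],
    n_enumerated = nrow(ends_mat),
    n_excluded = sum(degen),
    ends = ends_mat,
    posterior = post,
    log_norm = m + log(norm)
  ), class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("<posterior_summary> J = %d (%s): P(s*|x;J) = %.3f over %d segmentations\n",
              x$J, x$family, x$prob_opt, x$n_enumerated))
  if (length(x$opt_cp_years)) {
    cat(sprintf("  optimal change point(s): %s\n",
                paste(x$opt_cp_years, collapse = ", ")))
  }
  invisible(x)
}

#' Change-point posterior distribution (single change point)
#'
#' For `J = 2`, each segmentation is identified by its change point, so the
#' posterior over segmentations is a distribution over the `T - 1` candidate
#' change-point instants. The mode of this distribution is the optimal change
#' point, and its probability equals the posterior probability of the optimal
#' segmentation.
#'
#' @inheritParams segmentation_posterior
#' @return A `data.frame` with columns `tau` (index of the last observation of
#'   the first segment), `year` (calendar year of the first observation of the
#'   second segment) and `prob`; attributes `mode_tau`, `mode_year` and
#'   `prob_opt`.
#' @export
changepoint_posterior_distribution <- function(series,
                                               family = c("constant", "linear"),
                                               min_seg_len = 1, cap = 100) {
  family <- match.arg(family)
  ps <- segmentation_posterior(series, 2, family, min_seg_len = min_seg_len, cap = cap)
  sv <- as_series_values(series)
  tau <- ps$ends[, 1]
  out <- data.frame(tau = tau, year = sv$years[tau + 1L], prob = ps$posterior)
  i_mode <- which.max(out$prob)
  if (ps$prob_opt > 0) stopifnot(out$tau[i_mode] == ps$opt_ends[1])
  attr(out, "mode_tau") <- out$tau[i_mode]
  attr(out, "mode_year") <- out$year[i_mode]
  attr(out, "prob_opt") <- ps$prob_opt
  out
}
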