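# Model selection for homoscedastic Gaussian multiple change-point models:
# modified BIC (mBIC), Jeffreys' rule of thumb, model posterior probabilities,
# and the residual-series procedure that disambiguates a 2-segment constant
# model from a global linear trend.

#' Jeffreys decision threshold
#'
#' The mBIC difference required to deem one model substantially better than
#' another under Jeffreys' rules of thumb: `2 log(100) = 9.21`. The mBIC is on
#' the `2 log` scale, so this corresponds to a Bayes factor of 100.
#'
#' @return The numeric threshold.
#' @export
jeffreys_threshold <- function() 2 * log(100)

#' mBIC penalty term
#'
#' Penalty of the modified Bayesian information criterion for Gaussian
#' homoscedastic multiple change-point models, on the `2 log` scale. It
#' comprises a per-segment dimension term `d * sum(log n_j)` where `d` is the
#' number of within-segment parameters (1 for the constant family, 2 for the
#' linear family, each mean parameter being informed only by its own segment),
#' one `log n` for the pooled variance, and `2 log n` per change point for the
#' discrete location prior. Isolated here so alternative penalties can be
#' swapped in.
#'
#' @param n_seg Integer vector of per-segment non-missing counts.
#' @param family `"constant"` or `"linear"`.
#' @return The penalty (subtracted from twice the log-likelihood).
#' @export
mbic_penalty <- function(n_seg, family = c("constant", "linear")) {
  family <- match.arg(family)
  d <- if (family == "constant") 1 else 2
  n <- sum(n_seg)
  J <- length(n_seg)
  d * sum(log(n_seg)) + log(n) + 2 * (J - 1) * log(n)
}

mbic_of_fit <- function(fit) {
  if (fit$degenerate) {
    stop(errorCondition(
      "degenerate fit (zero residual variance): mBIC undefined",
      class = c("phenoseg_degenerate", "error", "condition")
    ))
  }
  2 * fit$loglik - mbic_penalty(fit$n_seg, fit$family)
}

#' Modified BIC of the optimal J-segment model
#'
#' Fits the optimal segmentation into `J` segments and returns its mBIC
#' (higher is better): twice the log-likelihood of the optimal segmentation
#' minus the [mbic_penalty()].
#'
#' @inheritParams optimal_segmentation
#' @return The mBIC value (scalar).
#' @export
compute_mbic <- function(series, J, family = c("constant", "linear"),
                         min_seg_len = NULL) {
  family <- match.arg(family)
  mbic_of_fit(optimal_segmentation(series, J, family, min_seg_len))
}

#' Compare two models by Jeffreys' rule of thumb
#'
#' The model with the higher mBIC is deemed substantially better if and only
#' if the difference is at least `2 log(100)` (inclusive); otherwise the two
#' models are indiscernible.
#'
#' @param mbic_a,mbic_b mBIC values of the two models.
#' @return A list with `verdict` (`"a"`, `"b"` or `"indiscernible"`),
#'   `difference` (`mbic_a - mbic_b`) and `threshold`.
#' @export
jeffreys_verdict <- function(mbic_a, mbic_b) {
  stopifnot(is.finite(mbic_a), is.finite(mbic_b))
  d <- mbic_a - mbic_b
  verdict <- if (abs(d) >= jeffreys_threshold()) {
    if (d > 0) "a" else "b"
  } else {
    "indiscernible"
  }
  list(verdict = verdict, difference = d, threshold = jeffreys_threshold())
}

#' Posterior probabilities of the number of segments
#'
#' Weights of the J-segment models for `J = 1, ..., J_max` within one family,
#' deduced from the mBIC under equal prior weights: since the mBIC
#' approximates twice the log marginal likelihood,
#' `P(M_J | x) = exp(mBIC_J / 2) / sum_J' exp(mBIC_J' / 2)`, computed stably
#' by max-shifting. An mBIC difference of `2 log(100)` therefore maps to
#' posterior odds of 100. Values of `J` that are infeasible for the series are
#' dropped.
#'
#' @inheritParams optimal_segmentation
#' @param J_max Largest number of segments considered (default 3).
#' @return Named numeric vector of probabilities (names are `J`), summing to 1.
#' @export
model_posteriors <- function(series, J_max = 3, family = c("constant", "linear"),
                             min_seg_len = NULL) {
  family <- match.arg(family)
  mb <- mbic_table(series, J_max, family, min_seg_len)
  if (!nrow(mb)) stop("no feasible model", call. = FALSE)
  z <- mb$mbic / 2
  p <- exp(z - max(z))
  p <- p / sum(p)
  stats::setNames(p, mb$J)
}

# mBIC for J = 1..J_max within one family; infeasible or degenerate J skipped.
mbic_table <- function(series, J_max, family, min_seg_len = NULL) {
  rows <- list()
  for (J in seq_len(J_max)) {
    fit <- tryCatch(optimal_segmentation(series, J, family, min_seg_len),
                    error = function(e) NULL)
    if (is.null(fit)) next
    mb <- tryCatch(mbic_of_fit(fit), phenoseg_degenerate = function(e) NA_real_)
    if (is.na(mb)) next
    rows[[length(rows) + 1L]] <- list(J = J, mbic = mb, fit = fit)
  }
  data.frame(
    J = vapply(rows, `[[`, integer(1), "J"),
    mbic = vapply(rows, `[[`, numeric(1), "mbic"),
    fit = I(lapply(rows, `[[`, "fit"))
  )
}

#' Select a change-point model across families
#'
#' Computes the mBIC for `J = 1, ..., J_max` in each requested family, selects
#' the best `J` per family, and compares the family winners with
#' [jeffreys_verdict()]. The overall selected model is the one with the
#' highest mBIC; when the family winners are indiscernible the comparison is
#' flagged so that downstream analyses (e.g. the residual procedure,
#' [residual_trend_procedure()]) can adjudicate.
#'
#' @inheritParams model_posteriors
#' @param families Character vector among `"constant"`, `"linear"`.
#' @return An object of class `model_comparison`: a list with `table`
#'   (family, J, mBIC), `best` (per-family best fit and mBIC), `posteriors`
#'   (per-family [model_posteriors()]), `selected` (family, J, mBIC, fit) and
#'   `verdict` (cross-family Jeffreys comparison, `NULL` if one family).
#' @export
select_segment_model <- function(series, J_max = 3,
                                 families = c("constant", "linear"),
                                 min_seg_len = NULL) {
  families <- match.arg(families, FAMILIES, several.ok = TRUE)
  tabs <- list(); best <- list(); post <- list()
  for (fam in families) {
    tb <- mbic_table(series, J_max, fam, min_seg_len)
    if (!nrow(tb)) next
    tabs[[fam]] <- data.frame(family = fam, J = tb$J, mbic = tb$mbic)
    i <- which.max(tb$mbic)
    best[[fam]] <- list(J = tb$J[i], mbic = tb$mbic[i], fit = tb$fit[[i]])
    z <- tb$mbic / 2
    p <- exp(z - max(z)); p <- p / sum(p)
    post[[fam]] <- stats::setNames(p, tb$J)
  }
  if (!length(best)) {
    stop(errorCondition("no non-degenerate model could be fitted",
                        class = c("phenoseg_degenerate", "error", "condition")))
  }
  verdict <- NULL
  if (length(best) == 2) {
    verdict <- jeffreys_verdict(best[[1]]$mbic, best[[2]]$mbic)
    verdict$families <- names(best)
  }
  sel_fam <- names(best)[which.max(vapply(best, `[[`, numeric(1), "mbic"))]
  structure(list(
    table = do.call(rbind, tabs),
    best = best,
    posteriors = post,
    selected = c(list(family = sel_fam), best[[sel_fam]]),
    verdict = verdict
  ), class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison>\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("selected: %s family, J = %d (mBIC %.2f)\n",
              x$selected$family, x$selected$J, x$selected$mbic))
  if (!is.null(x$verdict)) {
    cat(sprintf("cross-family verdict: %s (difference %.2f, threshold %.2f)\n",
                x$verdict$verdict, x$verdict$difference, x$verdict$threshold))
  }
  invisible(x)
}

#' Residual-series procedure
#'
#' Disambiguates the frequent stalemate between a 2-segment piecewise constant
#' model and a simple linear trend: a global linear model is fitted to the
#' series, the residual series is extracted, and the best piecewise *linear*
#' model for the residuals is selected by mBIC. A residual change point
#' between two within-segment trends indicates that the series contains a
#' level shift on top of (or instead of) the apparent global trend; a
#' stationary residual series with near-zero slope supports the plain trend.
#'
#' @inheritParams model_posteriors
#' @return A list with the global fit (`global_alpha`, `global_beta`), the
#'   residual [year_series()], the selected residual fit (`residual_fit`, a
#'   `segmentation_fit`, or `NULL` if degenerate), `residual_J`, the residual
#'   mBIC table and a `degenerate` flag.
#' @export
residual_trend_procedure <- function(series, J_max = 3, min_seg_len = NULL) {
  sv <- as_series_values(series)
  T <- length(sv$x)
  global <- refit_segmentation(series, T, "linear")
  fitted <- global$alpha[1] + global$beta[1] * sv$t
  resid <- year_series(sv$years, sv$x - fitted,
                       label = paste0(sv$label, " residuals"))
  tb <- mbic_table(resid, J_max, "linear", min_seg_len)
  if (!nrow(tb)) {
    return(list(global_alpha = global$alpha[1], global_beta = global$beta[1],
                residuals = resid, residual_fit = NULL, residual_J = NA_integer_,
                residual_mbic = NULL, degenerate = TRUE))
  }
  i <- which.max(tb$mbic)
  list(global_alpha = global$alpha[1], global_beta = global$beta[1],
       residuals = resid, residual_fit = tb$fit[[i]], residual_J = tb$J[i],
       residual_mbic = data.frame(J = tb$J, mbic = tb$mbic), degenerate = FALSE)
}

#' Per-segment slope significance
#'
#' Two-sided t-test of zero slope in each segment of a linear-family fit,
#' using the pooled (homoscedastic) residual variance with
#' `df = n - 2J` degrees of freedom. Segments on which the test cannot be
#' computed (exact fit, too few points) are flagged not assessable.
#'
#' @param fit A linear-family `segmentation_fit`.
#' @param level Significance level (default 0.05).
#' @return A `data.frame` with one row per segment: `beta`, `se`, `t`, `df`,
#'   `p`, `significant`, `assessable`.
#' @export
slope_significance <- function(fit, level = 0.05) {
  stopifnot(inherits(fit, "segmentation_fit"))
  if (fit$family != "linear") {
    stop("slope test requires a linear-family fit", call. = FALSE)
  }
  J <- fit$J
  df <- fit$n_obs - 2 * J
  s2 <- if (df >= 1) fit$rss_total / df else NA_real_
  out <- data.frame(segment = seq_len(J), beta = fit$beta,
                    se = NA_real_, t = NA_real_, df = df, p = NA_real_,
                    significant = NA, assessable = FALSE)
  for (j in seq_len(J)) {
    if (is.na(s2) || s2 <= 0 || !is.finite(fit$stt[j]) || fit$stt[j] <= 0) next
    se <- sqrt(s2 / fit$stt[j])
    tval <- fit$beta[j] / se
    p <- 2 * stats::pt(-abs(tval), df)
    out$se[j] <- se; out$t[j] <- tval; out$p[j] <- p
    out$significant[j] <- p < level
    out$assessable[j] <- TRUE
  }
  out
}
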