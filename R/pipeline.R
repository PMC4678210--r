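# Per-series orchestration: model selection across families, interpretability
# filtering of very short segments, the always-reported 2-segment constant
# summary used for cross-location comparison, flowering-duration analysis and
# flowering-temperature correlations.

#' Filter uninterpretably short segments
#'
#' Very short segments (a couple of years at one end of a series) cannot be
#' interpreted in a phenological context even when they are statistically
#' optimal. Any segment shorter than `min_len` years flags the segmentation;
#' the fallback removes the change point bounding the offending segment —
#' merging a leading short segment into its successor, a trailing one into
#' its predecessor — and refits, repeating until all segments are long enough
#' (possibly down to a single segment).
#'
#' @param fit A `segmentation_fit`.
#' @param series The series the fit was computed on.
#' @param min_len Minimum interpretable segment length in years (default 5).
#' @return A list with `flagged` (any segment was short), `fit` (the retained
#'   fit, possibly merged), `dropped_cp_years` (change points removed).
#' @export
short_segment_filter <- function(fit, series, min_len = 5) {
  stopifnot(inherits(fit, "segmentation_fit"))
  dropped <- integer(0)
  cur <- fit
  flagged <- FALSE
  repeat {
    lens <- cur$seg_lengths
    short <- which(lens < min_len)
    if (!length(short) || cur$J == 1) break
    flagged <- TRUE
    s <- short[1]
    # remove the change point bounding the short segment: leading segments
    # merge forward, others merge backward
    drop_idx <- if (s == 1) 1L else s - 1L
    dropped <- c(dropped, cur$cp_years[drop_idx])
    new_ends <- cur$ends[-drop_idx]
    cur <- refit_segmentation(series, new_ends, cur$family)
  }
  list(flagged = flagged, fit = cur, dropped_cp_years = dropped)
}

#' Analyse one annual series
#'
#' Full per-series analysis: mBIC model selection over both families and
#' `J = 1..J_max`, cross-family comparison by Jeffreys' rule with the
#' residual-series procedure run on stalemates between the 2-segment constant
#' model and the simple linear trend, short-segment interpretability
#' filtering, and the always-computed 2-segment piecewise constant summary
#' (change-point year, amplitude, global standard deviation, posterior
#' probability of the optimal segmentation and of the 2-segment model) used
#' for cross-location comparison.
#'
#' The retained working model is the constant-family mBIC selection (after
#' short-segment filtering): piecewise constant models are the primary
#' reading, and the linear family overrides only when it is substantially
#' better under Jeffreys' rule. A change point is reported as detected when
#' the retained model has two or more segments, or when a cross-family
#' stalemate's residual series itself segments into distinct trends.
#'
#' @param series A [year_series()] with at least 10 non-missing values.
#' @param families Model families to compare.
#' @param J_max Largest number of segments considered (default 3).
#' @param min_interpretable Minimum interpretable segment length in years
#'   (default 5), see [short_segment_filter()].
#' @param min_seg_len Minimum raw segment length for the optimisation
#'   (family default if `NULL`).
#' @return An object of class `series_report` (a list of plain values, so it
#'   survives a JSON round trip): label, observation period, mBIC table,
#'   selected model, retained model after filtering, cross-family verdict,
#'   residual-procedure summary (when run), the 2-segment constant summary and
#'   logical flags.
#' @export
analyze_series <- function(series, families = c("constant", "linear"),
                           J_max = 3, min_interpretable = 5,
                           min_seg_len = NULL) {
  stopifnot(inherits(series, "year_series"))
  assert_segmentable(series)
  report <- list(
    label = series$label,
    period = range(series$years),
    n_years = length(series$years),
    n_obs = n_obs(series),
    flags = list(degenerate = FALSE, short_segment = FALSE,
                 indiscernible_families = FALSE, discarded_changepoint = FALSE)
  )
  cmp <- tryCatch(
    select_segment_model(series, J_max = J_max, families = families,
                         min_seg_len = min_seg_len),
    phenoseg_degenerate = function(e) NULL
  )
  if (is.null(cmp)) {
    report$flags$degenerate <- TRUE
    report$changepoint_detected <- FALSE
    class(report) <- "series_report"
    return(report)
  }
  report$mbic <- cmp$table
  rownames(report$mbic) <- NULL
  report$selected <- list(family = cmp$selected$family, J = cmp$selected$J,
                          mbic = cmp$selected$mbic)
  report$model_posteriors <- lapply(cmp$posteriors, function(p) {
    stats::setNames(as.numeric(p), names(p))
  })
  if (!is.null(cmp$verdict)) {
    report$verdict <- list(
      verdict = if (cmp$verdict$verdict == "indiscernible") "indiscernible"
                else cmp$verdict$families[match(cmp$verdict$verdict, c("a", "b"))],
      difference = cmp$verdict$difference
    )
    report$flags$indiscernible_families <- cmp$verdict$verdict == "indiscernible"
  }

  # Retained working model: the constant family is primary; the linear family
  # replaces it only when substantially better by Jeffreys' rule (an mBIC
  # edge below 2 log(100) between the family winners is not conclusive).
  primary <- cmp$best$constant
  if (is.null(primary)) {
    primary <- cmp$best$linear
  } else if (!is.null(cmp$verdict) && cmp$verdict$verdict != "indiscernible" &&
             cmp$verdict$families[match(cmp$verdict$verdict, c("a", "b"))] == "linear") {
    primary <- cmp$best$linear
  }

  # interpretability filter on the retained model
  filt <- short_segment_filter(primary$fit, series, min_len = min_interpretable)
  report$flags$short_segment <- filt$flagged
  ret <- filt$fit
  report$retained <- list(
    family = ret$family, J = ret$J,
    cp_years = as.integer(ret$cp_years),
    amplitudes = as.numeric(ret$amplitudes),
    seg_means = as.numeric(ret$seg_means),
    slopes = as.numeric(ret$beta),
    sd = ret$sd,
    dropped_cp_years = as.integer(filt$dropped_cp_years)
  )

  # residual procedure on the classic stalemate: 2-segment constant vs
  # 1-segment linear, not discernible by mBIC
  residual_detected <- FALSE
  stalemate <- !is.null(cmp$verdict) && cmp$verdict$verdict == "indiscernible" &&
    !is.null(cmp$best$constant) && !is.null(cmp$best$linear) &&
    cmp$best$constant$J == 2 && cmp$best$linear$J == 1
  if (stalemate) {
    rp <- residual_trend_procedure(series, J_max = J_max, min_seg_len = min_seg_len)
    if (!rp$degenerate) {
      residual_detected <- rp$residual_J >= 2
      report$residual <- list(
        global_slope = rp$global_beta,
        residual_J = rp$residual_J,
        residual_cp_years = as.integer(if (rp$residual_J > 1) rp$residual_fit$cp_years else integer(0)),
        residual_slopes = as.numeric(rp$residual_fit$beta)
      )
    }
  }

  report$changepoint_detected <- (ret$J >= 2) || residual_detected

  # comparability summary: the 2-segment piecewise constant model
  two <- tryCatch(optimal_segmentation(series, 2, "constant"),
                  error = function(e) NULL)
  if (!is.null(two) && !two$degenerate) {
    post2 <- tryCatch(
      segmentation_posterior(series, 2, "constant", min_seg_len = 1),
      error = function(e) NULL
    )
    pmod <- report$model_posteriors$constant
    p2 <- if (!is.null(pmod) && "2" %in% names(pmod)) unname(pmod["2"]) else NA_real_
    f2 <- short_segment_filter(two, series, min_len = min_interpretable)
    if (f2$flagged) report$flags$discarded_changepoint <- TRUE
    report$two_segment <- list(
      cp_year = as.integer(two$cp_years),
      amplitude = unname(two$amplitudes),
      sd = two$sd,
      prob_segmentation = if (is.null(post2)) NA_real_ else post2$prob_opt,
      prob_model = p2,
      flagged_short = f2$flagged,
      supported = isTRUE(!f2$flagged && !is.na(p2) && p2 >= 1 / 3)
    )
  }
  class(report) <- "series_report"
  report
}

#' @export
print.series_report <- function(x, ...) {
  cat(sprintf("<series_report> %s (%d-%d, n = %d)\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              x$period[1], x$period[2], x$n_obs))
  if (x$flags$degenerate) {
    cat("  degenerate series (zero residual variance); no model selected\n")
    return(invisible(x))
  }
  cat(sprintf("  selected: %s, J = %d (mBIC %.2f)%s\n", x$selected$family,
              x$selected$J, x$selected$mbic,
              if (x$flags$indiscernible_families) " [families indiscernible]" else ""))
  if (x$retained$J > 1) {
    cat(sprintf("  retained change point(s): %s (amplitude %s), sd %.2f\n",
                paste(x$retained$cp_years, collapse = ", "),
                paste(sprintf("%.2f", x$retained$amplitudes), collapse = ", "),
                x$retained$sd))
  } else {
    cat(sprintf("  retained: single segment, sd %.2f\n", x$retained$sd))
  }
  if (!is.null(x$two_segment)) {
    cat(sprintf("  2-segment summary: change %d, amplitude %.2f, P(s*|x;2) = %.2f, P(M2|x) = %.2f%s\n",
                x$two_segment$cp_year, x$two_segment$amplitude,
                x$two_segment$prob_segmentation, x$two_segment$prob_model,
                if (x$two_segment$flagged_short) " [short segment, discarded]" else ""))
  }
  cat(sprintf("  change point detected: %s\n", x$changepoint_detected))
  invisible(x)
}

#' Write / read a series report as JSON
#'
#' Reports contain only plain values, so the JSON round trip preserves all
#' fields.
#'
#' @param report A `series_report`.
#' @param path Output (input) path.
#' @return `write_series_report` returns `path` invisibly;
#'   `read_series_report` returns the `series_report`.
#' @export
write_series_report <- function(report, path) {
  stopifnot(inherits(report, "series_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' @rdname write_series_report
#' @export
read_series_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(obj$mbic)) obj$mbic <- as.data.frame(obj$mbic)
  if (!is.null(obj$model_posteriors)) {
    obj$model_posteriors <- lapply(obj$model_posteriors, unlist)
  }
  obj$period <- as.integer(obj$period)
  # empty vectors come back as empty lists; restore the original types
  if (!is.null(obj$retained)) {
    for (f in c("cp_years", "dropped_cp_years")) {
      obj$retained[[f]] <- as.integer(unlist(obj$retained[[f]]))
    }
    for (f in c("amplitudes", "seg_means", "slopes")) {
      obj$retained[[f]] <- as.numeric(unlist(obj$retained[[f]]))
    }
  }
  if (!is.null(obj$residual)) {
    obj$residual$residual_cp_years <- as.integer(unlist(obj$residual$residual_cp_years))
    obj$residual$residual_slopes <- as.numeric(unlist(obj$residual$residual_slopes))
  }
  class(obj) <- "series_report"
  obj
}

#' Flowering-duration analysis
#'
#' Durations are the per-year differences between the full-bloom (BBCH 65) and
#' beginning-of-bloom (BBCH 61) dates, over the years where both stages were
#' observed. The duration series undergoes the full model selection; the
#' sample is called stationary when the 1-segment constant model is selected
#' (or when the durations are exactly constant). The Pearson correlation
#' between the two stage-date series over the common years is also reported.
#'
#' @param stage61,stage65 [year_series()] of stage dates (day of year).
#' @param J_max Passed to [select_segment_model()].
#' @return An object of class `duration_sample`: list with `label`, `years`,
#'   `durations`, `mean_duration`, `sd_duration`, `n`, `stationary`,
#'   `selected` (family and J, `NA` when degenerate) and `stage_correlation`.
#' @export
duration_analysis <- function(stage61, stage65, J_max = 3) {
  stopifnot(inherits(stage61, "year_series"), inherits(stage65, "year_series"))
  common <- intersect(stage61$years[!is.na(stage61$values)],
                      stage65$years[!is.na(stage65$values)])
  if (length(common) < MIN_SERIES_OBS) {
    stop(sprintf("only %d common observed years; at least %d required",
                 length(common), MIN_SERIES_OBS), call. = FALSE)
  }
  common <- sort(common)
  d61 <- stage61$values[match(common, stage61$years)]
  d65 <- stage65$values[match(common, stage65$years)]
  dur <- d65 - d61
  if (any(dur < 0)) {
    warning("negative flowering durations found (stage 65 before stage 61)",
            call. = FALSE)
  }
  dser <- year_series(common, dur, label = paste0(stage61$label, " duration"))
  cmp <- tryCatch(select_segment_model(dser, J_max = J_max),
                  phenoseg_degenerate = function(e) NULL)
  if (is.null(cmp)) {
    stationary <- TRUE  # constant durations: trivially no change point/trend
    selected <- list(family = NA_character_, J = NA_integer_)
  } else {
    stationary <- cmp$selected$family == "constant" && cmp$selected$J == 1
    selected <- list(family = cmp$selected$family, J = cmp$selected$J)
  }
  structure(list(
    label = stage61$label, years = common, durations = dur,
    mean_duration = mean(dur), sd_duration = stats::sd(dur), n = length(dur),
    stationary = stationary, selected = selected,
    stage_correlation = stats::cor(d61, d65)
  ), class = "duration_sample")
}

#' @export
print.duration_sample <- function(x, ...) {
  cat(sprintf("<duration_sample> %s: n = %d, mean %.2f d, %s, stage-date r = %.2f\n",
              x$label, x$n, x$mean_duration,
              if (x$stationary) "stationary" else "non-stationary",
              x$stage_correlation))
  invisible(x)
}

#' Pool duration samples across cultivars
#'
#' Samples (e.g. cultivars at one location) are pooled only when a
#' Kruskal-Wallis rank test cannot distinguish their frequency distributions
#' (`p >= level`).
#'
#' @param samples A list of `duration_sample` objects or numeric vectors.
#' @param level Significance level below which pooling is refused (default
#'   0.05).
#' @return A list with `pooled` (logical), `p_value`, `statistic`, and either
#'   `durations` (the pooled values) or `samples` (the refused inputs).
#' @export
pool_cultivars <- function(samples, level = 0.05) {
  stopifnot(is.list(samples), length(samples) >= 2)
  vals <- lapply(samples, function(s) {
    if (inherits(s, "duration_sample")) s$durations else as.numeric(s)
  })
  x <- unlist(vals)
  g <- factor(rep(seq_along(vals), lengths(vals)))
  if (length(unique(x)) == 1L) {
    # all observations identical: the rank test is vacuous, distributions agree
    return(list(pooled = TRUE, p_value = 1, statistic = 0, durations = x))
  }
  kw <- stats::kruskal.test(x, g)
  if (is.na(kw$p.value) || kw$p.value >= level) {
    list(pooled = TRUE, p_value = unname(kw$p.value), statistic = unname(kw$statistic),
         durations = x)
  } else {
    list(pooled = FALSE, p_value = unname(kw$p.value), statistic = unname(kw$statistic),
         samples = vals)
  }
}

#' Compare empirical cumulative distribution functions of duration samples
#'
#' @param samples Named list of `duration_sample` objects or numeric vectors.
#' @return A list with `ecdf` (named list of [stats::ecdf()] functions),
#'   `means` (named sample means), `ordering` (sample names by increasing
#'   mean) and `table` (long data frame of the step functions evaluated on
#'   the pooled integer grid).
#' @export
ecdf_compare <- function(samples) {
  stopifnot(is.list(samples), length(samples) >= 1)
  vals <- lapply(samples, function(s) {
    if (inherits(s, "duration_sample")) s$durations else as.numeric(s)
  })
  if (is.null(names(vals)) || any(!nzchar(names(vals)))) {
    names(vals) <- paste0("sample", seq_along(vals))
  }
  fns <- lapply(vals, stats::ecdf)
  means <- vapply(vals, mean, numeric(1))
  grid <- seq(floor(min(unlist(vals))), ceiling(max(unlist(vals))), by = 1)
  tab <- do.call(rbind, lapply(names(vals), function(nm) {
    data.frame(sample = nm, duration = grid, cumfreq = fns[[nm]](grid))
  }))
  list(ecdf = fns, means = means, ordering = names(sort(means)), table = tab)
}

#' Correlate flowering dates with period-mean temperatures
#'
#' Pearson (optionally Spearman) correlation between an annual flowering-date
#' series and an annual period-mean temperature series over their common
#' non-missing years, with the two-sided significance class used in
#' phenoclimatic tables: `**` at the 1% level, `*` at the 5% level, `n.s.`
#' otherwise.
#'
#' @param flowering,temperature [year_series()] objects.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A list with `r`, `p`, `n`, `class`, `method` and `years`.
#' @export
correlate_flowering_temperature <- function(flowering, temperature,
                                            method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(flowering, "year_series"), inherits(temperature, "year_series"))
  common <- intersect(flowering$years[!is.na(flowering$values)],
                      temperature$years[!is.na(temperature$values)])
  if (length(common) < MIN_SERIES_OBS) {
    stop(sprintf("only %d common observed years; at least %d required",
                 length(common), MIN_SERIES_OBS), call. = FALSE)
  }
  common <- sort(common)
  f <- flowering$values[match(common, flowering$years)]
  tmp <- temperature$values[match(common, temperature$years)]
  ct <- suppressWarnings(stats::cor.test(f, tmp, method = method))
  cls <- if (ct$p.value < 0.01) "**" else if (ct$p.value < 0.05) "*" else "n.s."
  list(r = unname(ct$estimate), p = ct$p.value, n = length(common),
       class = cls, method = method, years = common)
}
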