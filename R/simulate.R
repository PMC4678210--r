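# Seeded synthetic-data generators. The generators draw from the same model
# class the analysis fits -- Gaussian piecewise constant/linear annual series
# with i.i.d. noise -- plus a daily-temperature construction whose CA/HA
# period means reproduce prescribed annual series. Three scenario bundles
# emulate the contrasting phenoclimatic regimes the pipeline is meant to
# discriminate: temperate European (abrupt flowering advance driven by a heat
# -period warming step), mild Brazilian (everything stationary, flowering
# coupled to chill-period temperature) and Mediterranean (heat-period warming
# step whose effect on flowering is compensated, leaving it stationary).

#' Generate a piecewise Gaussian annual series
#'
#' Draws `x_t = alpha_j + beta_j * t + eps_t` with `eps ~ N(0, sigma^2)`
#' i.i.d., where `t` is the 0-based position in the series and `j` the segment
#' containing `t`. Deterministic under `seed`.
#'
#' @param years Integer vector of calendar years (strictly increasing), or a
#'   single length to mean `start_year + 0:(n-1)`.
#' @param levels Numeric vector of per-segment intercepts `alpha_j`.
#' @param changepoints Integer vector of segment end indices (last index of
#'   each segment except the final one); empty for a single segment.
#' @param slopes Per-segment slopes `beta_j` (recycled; default 0).
#' @param sigma Noise standard deviation (>= 0; 0 gives the noiseless limit).
#' @param missing_rate Probability that an observation is masked as missing.
#' @param start_year First calendar year when `years` is given as a length.
#' @param label Series label.
#' @param noise `"gaussian"` (default, the model class the analysis fits) or
#'   `"student"`, a heavy-tailed Student-t contamination for robustness
#'   probing, rescaled so its standard deviation is still `sigma`.
#' @param t_df Degrees of freedom of the Student-t noise (> 2; default 3).
#' @param seed Optional integer seed.
#' @return A [year_series()].
#' @export
generate_piecewise_series <- function(years, levels, changepoints = integer(0),
                                      slopes = 0, sigma, missing_rate = 0,
                                      start_year = 1974L, label = "synthetic",
                                      noise = c("gaussian", "student"),
                                      t_df = 3, seed = NULL) {
  noise <- match.arg(noise)
  if (length(years) == 1L) years <- start_year + 0:(years - 1L)
  T <- length(years)
  changepoints <- as.integer(changepoints)
  J <- length(changepoints) + 1L
  if (length(levels) != J) stop("`levels` must have one entry per segment", call. = FALSE)
  if (length(changepoints) &&
      (any(changepoints < 1L | changepoints >= T) ||
       is.unsorted(changepoints, strictly = TRUE))) {
    stop("`changepoints` must be strictly increasing indices in 1..T-1", call. = FALSE)
  }
  if (sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("`missing_rate` must be in [0, 1)", call. = FALSE)
  }
  slopes <- rep_len(slopes, J)
  if (!is.null(seed)) set.seed(seed)
  ends <- c(changepoints, T)
  seg <- rep(seq_len(J), times = diff(c(0L, ends)))
  t <- seq_len(T) - 1
  mu <- levels[seg] + slopes[seg] * t
  eps <- if (noise == "gaussian") {
    stats::rnorm(T, 0, sigma)
  } else {
    if (t_df <= 2) stop("`t_df` must exceed 2 for a finite variance", call. = FALSE)
    sigma * stats::rt(T, t_df) * sqrt((t_df - 2) / t_df)
  }
  x <- mu + eps
  if (missing_rate > 0) x[stats::runif(T) < missing_rate] <- NA_real_
  year_series(years, x, label = label)
}

#' Generate daily temperatures realising prescribed period means
#'
#' Builds a daily mean-temperature record as a seasonal sinusoid plus, inside
#' each period window, an annual offset chosen so that the window's mean
#' equals the prescribed annual value, plus i.i.d. daily noise. `tmin`/`tmax`
#' are the mean minus/plus half the diurnal range. With `daily_sd = 0`,
#' [aggregate_period_mean()] recovers the prescribed annual series exactly;
#' with noise, the period means deviate by about
#' `daily_sd / sqrt(window length)`.
#'
#' @param targets Named list of [year_series()] giving the desired annual
#'   period means.
#' @param periods Named list of [period_definition()]s with the same names;
#'   windows must not overlap.
#' @param seasonal_mean,seasonal_amplitude Annual-cycle baseline (degrees C).
#' @param winter_doy Day of year of the seasonal minimum (15 for the Northern
#'   Hemisphere, about 196 for the Southern).
#' @param daily_sd Standard deviation of daily noise.
#' @param diurnal_range `tmax - tmin` (degrees C).
#' @param seed Optional integer seed.
#' @return Daily records as from [daily_temperatures()].
#' @export
generate_daily_temperatures <- function(targets, periods, seasonal_mean = 10,
                                        seasonal_amplitude = 8, winter_doy = 15,
                                        daily_sd = 2, diurnal_range = 8,
                                        seed = NULL) {
  stopifnot(is.list(targets), is.list(periods),
            all(names(targets) %in% names(periods)))
  if (!is.null(seed)) set.seed(seed)
  windows <- list()
  for (nm in names(targets)) {
    ys <- targets[[nm]]
    for (k in seq_along(ys$years)) {
      if (is.na(ys$values[k])) next
      w <- period_window(periods[[nm]], ys$years[k])
      windows[[length(windows) + 1L]] <- list(start = w$start, end = w$end,
                                              value = ys$values[k])
    }
  }
  if (!length(windows)) stop("no target values to realise", call. = FALSE)
  d0 <- min(do.call(c, lapply(windows, `[[`, "start")))
  d1 <- max(do.call(c, lapply(windows, `[[`, "end")))
  grid <- seq(d0, d1, by = "day")
  doy <- as.integer(format(grid, "%j"))
  base <- seasonal_mean - seasonal_amplitude * cos(2 * pi * (doy - winter_doy) / 365.25)
  tmean <- base
  for (w in windows) {
    idx <- which(grid >= w$start & grid <= w$end)
    tmean[idx] <- tmean[idx] + (w$value - mean(base[idx]))
  }
  if (daily_sd > 0) tmean <- tmean + stats::rnorm(length(grid), 0, daily_sd)
  daily_temperatures(grid, tmean - diurnal_range / 2, tmean + diurnal_range / 2)
}

#' Generate a truncated-Gaussian flowering-duration sample
#'
#' @param n Sample size.
#' @param mean,sd Target mean and spread in days.
#' @param seed Optional integer seed.
#' @return Numeric vector of non-negative durations.
#' @export
generate_duration_sample <- function(n, mean, sd, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pmax(stats::rnorm(n, mean, sd), 0)
}

#' Scenario parameterisations
#'
#' The frozen parameter sets behind [generate_scenario_bundle()]; amplitudes,
#' standard deviations and series lengths follow the magnitudes typical of
#' long apple flowering and CA/HA temperature records in each regime (see the
#' methods vignette for the rationale behind each value).
#'
#' @param name `"european"`, `"brazilian"` or `"mediterranean"`.
#' @return A list of scenario parameters.
#' @export
scenario_spec <- function(name = c("european", "brazilian", "mediterranean")) {
  name <- match.arg(name)
  switch(name,
    european = list(
      name = "european", region = "europe", start_year = 1974L, n_years = 40L,
      winter_doy = 15, seasonal_mean = 9, seasonal_amplitude = 7,
      flowering = list(level = 110, amplitude = -8, cp = 20L, sigma = 6.7),
      ha = list(levels = c(7.5, 8.8), cp = 20L, sigma = 0.95, slopes = 0),
      ca = list(levels = 5.5, cp = integer(0), sigma = 1.0, slopes = 0.02),
      ha_coupling = -0.75,     # within-segment correlation flowering ~ HA
      duration = list(mean = 3.6, sd = 1.2)
    ),
    brazilian = list(
      name = "brazilian", region = "brazil", start_year = 1974L, n_years = 40L,
      winter_doy = 196, seasonal_mean = 13, seasonal_amplitude = 4,
      flowering = list(level = 245, amplitude = 0, cp = integer(0), sigma = 10),
      ha = list(levels = 14, cp = integer(0), sigma = 0.7, slopes = 0),
      ca = list(levels = 12, cp = integer(0), sigma = 0.8, slopes = 0),
      ca_coupling = 0.7,       # correlation flowering ~ CA (chill-driven delay)
      duration = list(mean = 10.5, sd = 3)
    ),
    mediterranean = list(
      name = "mediterranean", region = "europe", start_year = 1974L, n_years = 40L,
      winter_doy = 15, seasonal_mean = 10, seasonal_amplitude = 6.5,
      flowering = list(level = 105, amplitude = 0, cp = integer(0), sigma = 7),
      ha = list(levels = c(8.0, 9.31), cp = 14L, sigma = 0.88, slopes = 0),
      ca = list(levels = c(6.0, 7.0), cp = 14L, sigma = 1.0, slopes = 0),
      ha_coupling = -0.7,      # anomaly coupling only: step compensated by CA decline
      duration = list(mean = 2.8, sd = 1)
    )
  )
}

piecewise_mu <- function(spec_part, T) {
  ends <- c(spec_part$cp, T)
  J <- length(ends)
  seg <- rep(seq_len(J), times = diff(c(0L, ends)))
  slopes <- rep_len(spec_part$slopes, J)
  spec_part$levels[seg] + slopes[seg] * (seq_len(T) - 1)
}

#' Generate a full scenario bundle
#'
#' Draws, for one pseudo-location, the annual flowering-date series (stages 61
#' and 65), the flowering-duration sample, annual CA/HA period-mean targets
#' and the daily temperature record realising them. Flowering is coupled to
#' the temperature series according to the scenario: in the European scenario
#' it carries its own advance step and responds to heat-period anomalies; in
#' the Brazilian scenario it is stationary and positively coupled to the
#' chill-period mean; in the Mediterranean scenario it responds only to
#' heat-period *anomalies* about the segment means, so the warming step is not
#' transmitted and flowering stays stationary. Pure function of
#' `(name, seed)`.
#'
#' @param name Scenario name, see [scenario_spec()].
#' @param seed Integer seed.
#' @param n_years Series length (default 40).
#' @return A list with `scenario`, `years`, `flowering` (stage 61),
#'   `stage65`, `durations`, `ca_target`, `ha_target` ([year_series()]),
#'   `daily` (daily records), `periods` and `truth` (the generating values).
#' @export
generate_scenario_bundle <- function(name, seed, n_years = NULL) {
  sp <- scenario_spec(name)
  if (!is.null(n_years)) sp$n_years <- as.integer(n_years)
  T <- sp$n_years
  years <- sp$start_year + 0:(T - 1)
  set.seed(seed)

  ha_mu <- piecewise_mu(sp$ha, T)
  ca_mu <- piecewise_mu(sp$ca, T)
  ha_vals <- ha_mu + stats::rnorm(T, 0, sp$ha$sigma)
  ca_vals <- ca_mu + stats::rnorm(T, 0, sp$ca$sigma)
  ha_target <- year_series(years, ha_vals, label = "HA")
  ca_target <- year_series(years, ca_vals, label = "CA")

  fl <- sp$flowering
  fl_mu <- fl$level + if (length(fl$cp)) fl$amplitude * (seq_len(T) > fl$cp) else 0
  if (!is.null(sp$ha_coupling)) {
    rho <- sp$ha_coupling
    b <- rho * fl$sigma / sp$ha$sigma
    resid_sd <- fl$sigma * sqrt(1 - rho^2)
    fl_vals <- fl_mu + b * (ha_vals - ha_mu) + stats::rnorm(T, 0, resid_sd)
  } else if (!is.null(sp$ca_coupling)) {
    rho <- sp$ca_coupling
    z_ca <- (ca_vals - ca_mu) / sp$ca$sigma
    fl_vals <- fl_mu + fl$sigma * (rho * z_ca + sqrt(1 - rho^2) * stats::rnorm(T))
  } else {
    fl_vals <- fl_mu + stats::rnorm(T, 0, fl$sigma)
  }
  flowering <- year_series(years, fl_vals, label = paste0(name, " stage 61"))

  durations <- pmax(stats::rnorm(T, sp$duration$mean, sp$duration$sd), 0)
  stage65 <- year_series(years, fl_vals + durations,
                         label = paste0(name, " stage 65"))

  periods <- period_preset(sp$region)
  daily <- generate_daily_temperatures(
    targets = list(ca = ca_target, ha = ha_target),
    periods = periods,
    seasonal_mean = sp$seasonal_mean, seasonal_amplitude = sp$seasonal_amplitude,
    winter_doy = sp$winter_doy, daily_sd = 2, diurnal_range = 8
  )

  list(
    scenario = name, years = years, flowering = flowering, stage65 = stage65,
    durations = durations, ca_target = ca_target, ha_target = ha_target,
    daily = daily, periods = periods,
    truth = list(
      flowering_cp_index = if (length(fl$cp)) fl$cp else NA_integer_,
      flowering_cp_year = if (length(fl$cp)) years[fl$cp + 1L] else NA_integer_,
      flowering_amplitude = fl$amplitude,
      ha_cp_index = if (length(sp$ha$cp)) sp$ha$cp else NA_integer_,
      ha_cp_year = if (length(sp$ha$cp)) years[sp$ha$cp + 1L] else NA_integer_,
      ha_amplitude = if (length(sp$ha$cp)) diff(sp$ha$levels)[1] else 0,
      ca_cp_index = if (length(sp$ca$cp)) sp$ca$cp else NA_integer_
    )
  )
}

#' Run a scenario bundle through the full pipeline
#'
#' Aggregates the bundle's daily temperatures into CA/HA annual means,
#' analyses the flowering and HA series with [analyze_series()], computes the
#' flowering-CA and flowering-HA correlations, and evaluates whether the
#' qualitative pattern expected for the scenario is reproduced:
#' \describe{
#'   \item{european}{change point detected in flowering with negative
#'     amplitude, and significant negative flowering-HA correlation;}
#'   \item{brazilian}{no flowering change point, and significant positive
#'     flowering-CA correlation;}
#'   \item{mediterranean}{no flowering change point although the HA series
#'     carries a supported warming step (2-segment model retained).}
#' }
#'
#' @inheritParams generate_scenario_bundle
#' @return A list with the bundle, the per-series reports, both correlations
#'   and `pattern_matched` (logical).
#' @export
evaluate_scenario <- function(name, seed, n_years = NULL) {
  b <- generate_scenario_bundle(name, seed, n_years)
  ca <- aggregate_period_mean(b$daily, b$periods$ca)
  ha <- aggregate_period_mean(b$daily, b$periods$ha)
  fl_rep <- analyze_series(b$flowering)
  ha_rep <- analyze_series(ha)
  cor_ca <- correlate_flowering_temperature(b$flowering, ca)
  cor_ha <- correlate_flowering_temperature(b$flowering, ha)
  matched <- switch(b$scenario,
    european = isTRUE(
      fl_rep$changepoint_detected &&
      fl_rep$two_segment$amplitude < 0 &&
      cor_ha$class != "n.s." && cor_ha$r < 0
    ),
    brazilian = isTRUE(
      !fl_rep$changepoint_detected &&
      cor_ca$class != "n.s." && cor_ca$r > 0
    ),
    mediterranean = isTRUE(
      !fl_rep$changepoint_detected &&
      !is.null(ha_rep$two_segment) && ha_rep$two_segment$supported
    )
  )
  list(scenario = b$scenario, bundle = b, ca = ca, ha = ha,
       flowering_report = fl_rep, ha_report = ha_rep,
       cor_ca = cor_ca, cor_ha = cor_ha, pattern_matched = matched)
}
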