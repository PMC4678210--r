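#' Read daily temperature records from CSV
#'
#' Expects columns `date` (ISO-8601), `tmin`, `tmax` in degrees Celsius. The
#' daily mean is derived as `(tmin + tmax) / 2`, the convention used for
#' weather-station summaries in phenoclimatic work.
#'
#' @param path Path to a CSV file.
#' @return A `data.frame` with columns `date` (`Date`), `tmin`, `tmax`,
#'   `tmean`, sorted by date.
#' @export
read_daily_temperatures <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "tmin", "tmax")
  if (!all(need %in% names(df))) {
    stop("expected columns: date, tmin, tmax", call. = FALSE)
  }
  daily_temperatures(as.Date(df$date), as.numeric(df$tmin), as.numeric(df$tmax))
}

#' Assemble a daily temperature record table
#'
#' @param date `Date` vector, unique.
#' @param tmin,tmax Daily minimum and maximum temperature (degrees C); `NA`
#'   marks a missing day.
#' @return A `data.frame` with `date`, `tmin`, `tmax` and derived `tmean`.
#' @export
daily_temperatures <- function(date, tmin, tmax) {
  date <- as.Date(date)
  if (anyNA(date)) stop("unparseable dates in daily records", call. = FALSE)
  if (anyDuplicated(date)) stop("duplicate dates in daily records", call. = FALSE)
  bad <- which(!is.na(tmin) & !is.na(tmax) & tmin > tmax)
  if (length(bad)) {
    stop(sprintf("tmin > tmax on %s", format(date[bad[1]])), call. = FALSE)
  }
  ord <- order(date)
  df <- data.frame(date = date[ord], tmin = as.numeric(tmin)[ord],
                   tmax = as.numeric(tmax)[ord])
  df$tmean <- (df$tmin + df$tmax) / 2
  df
}

#' Linearly interpolate missing days in a temperature record
#'
#' Missing days (absent rows or `NA` cells) are filled by linear interpolation
#' of `tmin` and `tmax` separately across the gap; `tmean` is recomputed.
#' Interpolation is only allowed for interior gaps bounded by observed days;
#' gaps longer than `max_gap` consecutive days are refused rather than
#' fabricating long stretches of data.
#'
#' @param records Daily records as returned by [daily_temperatures()].
#' @param max_gap Maximum gap length, in days, that may be interpolated
#'   (default 10).
#' @return Records on the complete daily grid with gaps filled.
#' @export
interpolate_missing_daily <- function(records, max_gap = 10) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  grid <- seq(min(records$date), max(records$date), by = "day")
  idx <- match(grid, records$date)
  out <- data.frame(date = grid,
                    tmin = records$tmin[idx],
                    tmax = records$tmax[idx])
  for (col in c("tmin", "tmax")) {
    y <- out[[col]]
    miss <- is.na(y)
    if (!any(miss)) next
    if (miss[1] || miss[length(y)]) {
      stop(sprintf("gap at series boundary in %s cannot be interpolated", col),
           call. = FALSE)
    }
    runs <- rle(miss)
    gap_len <- max(runs$lengths[runs$values])
    if (gap_len > max_gap) {
      stop(sprintf("gap of %d days in %s exceeds max_gap = %d",
                   gap_len, col, max_gap), call. = FALSE)
    }
    out[[col]] <- stats::approx(as.numeric(grid)[!miss], y[!miss],
                                xout = as.numeric(grid))$y
  }
  out$tmean <- (out$tmin + out$tmax) / 2
  out
}

#' Define a chill- or heat-accumulation period
#'
#' A period is an annual calendar window (e.g. October--January for the
#' Northern-Hemisphere chill-accumulation period). A window crossing the year
#' boundary is labelled by the calendar year containing its *end*, i.e. the
#' year of the flowering season it feeds into, so that the aggregated value
#' aligns with that year's flowering date.
#'
#' @param name Period name, conventionally `"CA"` or `"HA"`.
#' @param start_month,start_day First day of the window (day defaults to 1).
#' @param end_month,end_day Last day of the window, inclusive; `end_day = NULL`
#'   means the last day of `end_month`. A half-month end such as "mid-April"
#'   is expressed as `end_day = 15`.
#' @return An object of class `period_definition`.
#' @examples
#' period_definition("CA", 10, 1, 1)          # Oct 1 -- Jan 31, labelled by Jan year
#' period_definition("HA", 3, 1, 4, 15)       # Mar 1 -- Apr 15
#' @export
period_definition <- function(name, start_month, start_day = 1,
                              end_month, end_day = NULL) {
  stopifnot(start_month %in% 1:12, end_month %in% 1:12)
  p <- structure(
    list(name = as.character(name), start_month = as.integer(start_month),
         start_day = as.integer(start_day), end_month = as.integer(end_month),
         end_day = if (is.null(end_day)) NA_integer_ else as.integer(end_day)),
    class = "period_definition"
  )
  # sanity: window must span at least 28 days (checked on a non-leap year)
  w <- period_window(p, 2001L)
  if (as.integer(w$end - w$start) + 1L < 28L) {
    stop("period must span at least 28 days", call. = FALSE)
  }
  p
}

#' @export
print.period_definition <- function(x, ...) {
  end_day <- if (is.na(x$end_day)) "end" else x$end_day
  cat(sprintf("<period> %s: %02d-%02d to %02d-%s (labelled by end year)\n",
              x$name, x$start_month, x$start_day, x$end_month,
              as.character(end_day)))
  invisible(x)
}

# Calendar window of a period for phenological year `year` (the year
# containing the window end).
period_window <- function(period, year) {
  crosses <- period$start_month > period$end_month
  start_year <- if (crosses) year - 1L else year
  start <- as.Date(sprintf("%04d-%02d-%02d", start_year,
                           period$start_month, period$start_day))
  end_day <- period$end_day
  if (is.na(end_day)) {
    first_next <- if (period$end_month == 12L) {
      as.Date(sprintf("%04d-01-01", year + 1L))
    } else {
      as.Date(sprintf("%04d-%02d-01", year, period$end_month + 1L))
    }
    end <- first_next - 1L
  } else {
    end <- as.Date(sprintf("%04d-%02d-%02d", year, period$end_month, end_day))
  }
  if (end <= start) stop("period start must precede its end", call. = FALSE)
  list(start = start, end = end)
}

#' Preset CA/HA period definitions by region
#'
#' Chill-accumulation (CA) and heat-accumulation (HA) windows used for apple
#' tree phenology: Europe CA October--January, HA February--April; Morocco
#' CA October--January, HA March--mid-April; Brazil (Southern Hemisphere)
#' CA April--July, HA August--October.
#'
#' @param region One of `"europe"`, `"morocco"`, `"brazil"`.
#' @return A list with elements `ca` and `ha`, both [period_definition()]s.
#' @export
period_preset <- function(region = c("europe", "morocco", "brazil")) {
  region <- match.arg(region)
  switch(region,
    europe = list(ca = period_definition("CA", 10, 1, 1),
                  ha = period_definition("HA", 2, 1, 4)),
    morocco = list(ca = period_definition("CA", 10, 1, 1),
                   ha = period_definition("HA", 3, 1, 4, 15)),
    brazil = list(ca = period_definition("CA", 4, 1, 7),
                  ha = period_definition("HA", 8, 1, 10))
  )
}

#' Read period definitions from a YAML configuration
#'
#' The configuration maps period names to `start_month`, `start_day`,
#' `end_month`, `end_day` fields, e.g.
#' \preformatted{
#' ca: {start_month: 10, end_month: 1}
#' ha: {start_month: 2, end_month: 4}
#' }
#'
#' @param path Path to a YAML file.
#' @return Named list of [period_definition()]s.
#' @export
read_period_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- lapply(names(cfg), function(nm) {
    p <- cfg[[nm]]
    period_definition(
      name = toupper(nm),
      start_month = p$start_month,
      start_day = if (is.null(p$start_day)) 1 else p$start_day,
      end_month = p$end_month,
      end_day = p$end_day
    )
  })
  names(out) <- names(cfg)
  out
}

#' Aggregate daily temperatures into annual period means
#'
#' Computes, for each phenological year covered by the records, the arithmetic
#' mean of the daily mean temperature over the period window. A year whose
#' window is incompletely covered (missing days or `NA` values) is marked
#' missing with a warning; run [interpolate_missing_daily()] first to fill
#' short gaps.
#'
#' @param records Daily records ([daily_temperatures()]).
#' @param period A [period_definition()].
#' @return A [year_series()] of period-mean temperatures, labelled by the
#'   period name, one value per phenological year whose window lies inside the
#'   record range.
#' @export
aggregate_period_mean <- function(records, period) {
  stopifnot(is.data.frame(records), inherits(period, "period_definition"))
  records <- records[order(records$date), ]
  dmin <- min(records$date); dmax <- max(records$date)
  y0 <- as.integer(format(dmin, "%Y")); y1 <- as.integer(format(dmax, "%Y")) + 1L
  years <- integer(0); values <- numeric(0)
  for (y in y0:y1) {
    w <- period_window(period, y)
    if (w$start < dmin || w$end > dmax) next
    expected <- as.integer(w$end - w$start) + 1L
    sel <- records$date >= w$start & records$date <= w$end
    got <- records$tmean[sel]
    years <- c(years, y)
    if (length(got) < expected || anyNA(got)) {
      warning(sprintf("period %s, year %d: incomplete coverage (%d/%d days); marked missing",
                      period$name, y, sum(!is.na(got)), expected), call. = FALSE)
      values <- c(values, NA_real_)
    } else {
      values <- c(values, mean(got))
    }
  }
  if (!length(years)) {
    stop(sprintf("records cover no complete %s window", period$name), call. = FALSE)
  }
  year_series(years, values, label = period$name)
}
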