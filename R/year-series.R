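#' Annual observation series
#'
#' Container for a year-indexed series of real-valued observations: flowering
#' dates as day-of-year, or period-mean temperatures in degrees Celsius.
#' Missing observations are stored as `NA` and are never interpolated
#' (interpolation is reserved for *daily* temperature records, see
#' [interpolate_missing_daily()]).
#'
#' @param years Integer vector of calendar years, strictly increasing.
#' @param values Numeric vector, same length as `years`; `NA` marks a missing
#'   observation, non-missing values must be finite.
#' @param label Character scalar identifying the series (location, cultivar,
#'   phenological stage or temperature period).
#'
#' @return An object of class `year_series`: a list with elements `label`,
#'   `years` and `values`.
#' @examples
#' ys <- year_series(1987:1989, c(105, 96, 94), label = "demo")
#' n_obs(ys)
#' @export
year_series <- function(years, values, label = "") {
  years <- as.integer(years)
  values <- as.numeric(values)
  if (length(years) != length(values)) {
    stop("`years` and `values` must have the same length", call. = FALSE)
  }
  if (anyNA(years)) stop("`years` must not contain NA", call. = FALSE)
  if (length(years) > 1 && any(diff(years) <= 0)) {
    stop("`years` must be strictly increasing", call. = FALSE)
  }
  if (any(!is.na(values) & !is.finite(values))) {
    stop("non-missing `values` must be finite", call. = FALSE)
  }
  structure(
    list(label = as.character(label)[1], years = years, values = values),
    class = "year_series"
  )
}

#' @export
length.year_series <- function(x) length(x$years)

#' Number of non-missing observations in a series
#' @param x A [year_series()].
#' @return Integer count of non-`NA` values.
#' @export
n_obs <- function(x) {
  stopifnot(inherits(x, "year_series"))
  sum(!is.na(x$values))
}

#' @export
print.year_series <- function(x, ...) {
  cat(sprintf(
    "<year_series> %s: %d years (%d-%d), %d observed\n",
    if (nzchar(x$label)) x$label else "(unlabelled)",
    length(x$years), min(x$years), max(x$years), n_obs(x)
  ))
  invisible(x)
}

#' @export
as.data.frame.year_series <- function(x, ...) {
  data.frame(year = x$years, value = x$values)
}

# Minimum number of non-missing observations for a series submitted to
# segmentation-based analyses.
MIN_SERIES_OBS <- 10L

assert_segmentable <- function(x) {
  if (n_obs(x) < MIN_SERIES_OBS) {
    stop(sprintf(
      "series '%s' has %d non-missing values; at least %d are required",
      x$label, n_obs(x), MIN_SERIES_OBS
    ), call. = FALSE)
  }
  invisible(x)
}

#' Read an annual series from CSV
#'
#' Expects a header row and one row per year with columns `year` and `value`
#' (or any two columns, taken in order). Empty or `NA` cells become missing
#' observations; they are recorded in the missing mask, never interpolated.
#'
#' @param path Path to a CSV file.
#' @param label Series label; defaults to the file name without extension.
#' @return A [year_series()].
#' @export
read_year_series <- function(path, label = NULL) {
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.csv(path, colClasses = "character",
                        strip.white = TRUE, check.names = FALSE)
  if (ncol(df) < 2) stop("expected at least two columns (year, value)", call. = FALSE)
  cols <- if (all(c("year", "value") %in% names(df))) c("year", "value") else names(df)[1:2]
  yr_raw <- df[[cols[1]]]
  val_raw <- df[[cols[2]]]
  years <- suppressWarnings(as.integer(yr_raw))
  bad_year <- which(is.na(years))
  if (length(bad_year)) {
    stop(sprintf("row %d: non-integer year '%s'", bad_year[1], yr_raw[bad_year[1]]),
         call. = FALSE)
  }
  dup <- years[duplicated(years)]
  if (length(dup)) {
    stop(sprintf("duplicate year(s): %s", paste(unique(dup), collapse = ", ")),
         call. = FALSE)
  }
  empty <- is.na(val_raw) | val_raw == "" | toupper(val_raw) == "NA"
  values <- rep(NA_real_, length(val_raw))
  parsed <- suppressWarnings(as.numeric(val_raw[!empty]))
  bad_val <- which(!empty)[is.na(parsed)]
  if (length(bad_val)) {
    stop(sprintf("row %d: non-numeric value '%s'", bad_val[1], val_raw[bad_val[1]]),
         call. = FALSE)
  }
  values[!empty] <- parsed
  ord <- order(years)
  year_series(years[ord], values[ord], label = label)
}

#' Write an annual series to CSV
#'
#' Writes the `year,value` dialect read by [read_year_series()]; missing
#' observations become empty cells.
#'
#' @param x A [year_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_year_series <- function(x, path) {
  stopifnot(inherits(x, "year_series"))
  df <- data.frame(year = x$years, value = ifelse(is.na(x$values), "", format(x$values, digits = 15, trim = TRUE)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
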