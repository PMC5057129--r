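# Core data model: one pixel's irregular spectral-index time series.
# Dates are stored as integer ordinal days (days since 1970-01-01, the
# base R Date epoch); decimal years use 365.25 days/year throughout.

DAYS_PER_YEAR <- 365.25

#' Convert ordinal days to decimal years
#'
#' @param day Integer ordinal days (days since 1970-01-01).
#' @return Decimal years (365.25 days per year).
#' @export
day_to_year <- function(day) 1970 + as.numeric(day) / DAYS_PER_YEAR

#' Convert decimal years to ordinal days
#'
#' @param year Decimal years.
#' @return Integer ordinal days (rounded).
#' @export
year_to_day <- function(year) as.integer(round((year - 1970) * DAYS_PER_YEAR))

#' Construct a pixel time series
#'
#' A `pixel_series` holds one pixel's irregular time series: observation
#' dates (integer ordinal days, strictly increasing), spectral-index values
#' (e.g. NDVI), and a per-date validity flag. Non-finite values are marked
#' invalid rather than rejected.
#'
#' @param day Integer ordinal days or `Date`s; strictly increasing.
#' @param value Numeric spectral-index values, same length as `day`.
#' @param valid Logical validity flags (default: all valid).
#' @return An object of class `pixel_series` with elements `day`, `value`,
#'   `valid`.
#' @examples
#' ps <- pixel_series(as.Date(c("2000-01-01", "2000-02-01")), c(0.8, 0.7))
#' n_valid(ps)
#' @export
pixel_series <- function(day, value, valid = rep(TRUE, length(day))) {
  if (inherits(day, "Date")) day <- as.integer(day)
  day <- as.integer(day)
  value <- as.numeric(value)
  valid <- as.logical(valid)
  if (length(day) < 1L) stop("pixel_series needs at least one observation")
  if (length(value) != length(day) || length(valid) != length(day))
    stop("day, value and valid must have the same length")
  if (is.unsorted(day, strictly = TRUE))
    stop("dates must be strictly increasing with no duplicates")
  valid[!is.finite(value)] <- FALSE
  structure(list(day = day, value = value, valid = valid),
            class = "pixel_series")
}

#' @export
print.pixel_series <- function(x, ...) {
  cat(sprintf("pixel_series: %d observations (%d valid), %s to %s\n",
              length(x$day), sum(x$valid),
              as.Date(min(x$day), origin = "1970-01-01"),
              as.Date(max(x$day), origin = "1970-01-01")))
  invisible(x)
}

#' @export
length.pixel_series <- function(x) length(x$day)

#' Number of valid observations
#' @param series A `pixel_series`.
#' @return Integer count of valid observations.
#' @export
n_valid <- function(series) sum(series$valid)

#' Drop invalid observations
#'
#' Returns the subseries of valid observations, order preserved. Idempotent;
#' an all-invalid input yields a zero-length series (not constructible via
#' [pixel_series()], but consistent for internal plumbing).
#'
#' @param series A `pixel_series`.
#' @return A `pixel_series` containing only the valid observations.
#' @export
drop_invalid <- function(series) {
  stopifnot(inherits(series, "pixel_series"))
  keep <- series$valid
  structure(list(day = series$day[keep], value = series$value[keep],
                 valid = series$valid[keep]),
            class = "pixel_series")
}

#' Normalized difference vegetation index
#'
#' NDVI = (NIR - Red) / (NIR + Red), clipped to \[-1, 1\]. Dates where the
#' denominator is zero or a band is non-finite return `NA` (to be flagged
#' invalid downstream). Negative reflectances are an input error.
#'
#' @param red,nir Surface reflectance in \[0, 1\] (vectors recycled to a
#'   common length).
#' @return NDVI values in \[-1, 1\], `NA` where undefined.
#' @examples
#' compute_ndvi(0.1, 0.4)  # 0.6
#' @export
compute_ndvi <- function(red, nir) {
  if (any(red < 0, na.rm = TRUE) || any(nir < 0, na.rm = TRUE))
    stop("reflectance must be non-negative")
  denom <- red + nir
  out <- (nir - red) / denom
  out[!is.finite(red) | !is.finite(nir) | denom == 0] <- NA_real_
  pmin(1, pmax(-1, out))
}

#' Time-series noise estimate
#'
#' The per-pixel noise scalar is the median of the absolute forward finite
#' differences of consecutive valid values. It internalizes atmospheric
#' contamination, geometric error and phenology, and is the denominator of
#' the bail-out ratio in [nita_fit()]. Absolute differences are used because
#' the statistic must represent noise magnitude (signed differences would
#' have median near zero).
#'
#' @param series A `pixel_series` with at least 2 valid observations.
#' @return Non-negative noise estimate in spectral-index units.
#' @examples
#' estimate_noise(pixel_series(1:4, c(0.1, 0.3, 0.2, 0.6)))  # 0.2
#' @export
estimate_noise <- function(series) {
  v <- series$value[series$valid]
  if (length(v) < 2L) stop("estimate_noise needs at least 2 valid observations")
  stats::median(abs(diff(v)))
}

#' Write a pixel series to delimited text
#'
#' Two-column whitespace-delimited format (`ordinal_day value`), invalid
#' observations omitted.
#'
#' @param series A `pixel_series`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pixel_series <- function(series, path) {
  s <- drop_invalid(series)
  utils::write.table(data.frame(ordinal_day = s$day, value = s$value),
                     path, row.names = FALSE, col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Read a pixel series from delimited text
#'
#' @param path File written by [write_pixel_series()].
#' @return A `pixel_series` (all observations valid).
#' @export
read_pixel_series <- function(path) {
  d <- utils::read.table(path, header = TRUE)
  pixel_series(d$ordinal_day, d$value)
}
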