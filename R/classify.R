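# Disturbance classification of fitted trajectories and landscape-level
# summaries (date-of-disturbance, cumulative disturbed area, correlation
# of annual disturbance rate with production).

#' Disturbance classification thresholds
#'
#' An event qualifies as a disturbance when the fitted NDVI drops from
#' above `high_ndvi` to below `low_ndvi` at a rate exceeding `rate_cut`
#' NDVI/year; the same level crossing at a lower rate is a decline.
#'
#' @param high_ndvi Upper NDVI level (default 0.70).
#' @param low_ndvi Lower NDVI level (default 0.40).
#' @param rate_cut Rate threshold in NDVI/year (default 0.10).
#' @param flat_tol Slope tolerance in NDVI/year: fitted segments with
#'   `slope > -flat_tol` are treated as flat when merging declining runs,
#'   so that noise-level drift in a post-disturbance plateau does not
#'   extend an event (default 0.01, a tenth of `rate_cut`).
#' @return An object of class `nita_thresholds`.
#' @export
nita_thresholds <- function(high_ndvi = 0.70, low_ndvi = 0.40,
                            rate_cut = 0.10, flat_tol = 0.01) {
  stopifnot(high_ndvi > low_ndvi, rate_cut > 0, flat_tol >= 0,
            flat_tol < rate_cut)
  structure(list(high_ndvi = high_ndvi, low_ndvi = low_ndvi,
                 rate_cut = rate_cut, flat_tol = flat_tol),
            class = "nita_thresholds")
}

#' Classify a fitted trajectory into disturbance/decline events
#'
#' Maximal runs of consecutive negative-slope segments are merged into
#' candidate events (cloud gaps often split one drop across two fitted
#' segments); segments with slope above `-flat_tol` break runs, so noise
#' drift in a plateau does not extend an event. Event values are taken
#' from the fitted breakpoints: the start is the last breakpoint in the
#' run at or above `high_ndvi` (the run's first breakpoint if none reaches
#' it). An event is a `disturbance` when the start value exceeds
#' `high_ndvi`, some run breakpoint falls below `low_ndvi`, and the
#' fastest start-to-below-threshold crossing exceeds `rate_cut` (a sharp
#' drop followed by slow drift is not diluted by the drift); a `decline`
#' when it makes the same crossing at a lower rate; otherwise `no_event`.
#' The reported
#' `date_of_nadir` is where the rapid decline bottoms out (the last
#' breakpoint below `low_ndvi` reached by a segment steeper than
#' `rate_cut`, or the run minimum for slow declines). `recovered` is
#' `TRUE` when any later breakpoint, after a positive-slope segment,
#' exceeds `low_ndvi`.
#'
#' @param model A `nita_model` (or any list with a `breakpoints` data frame
#'   of `day`, `value`).
#' @param thresholds A [nita_thresholds()] object.
#' @return A data frame with one row per declining run:
#'   `date_before_disturbance`, `date_of_nadir` (ordinal days), `start_value`,
#'   `nadir_value`, `magnitude`, `drop_rate` (NDVI/year), `event_class`
#'   (`"disturbance"`, `"decline"` or `"no_event"`), `recovered`. Zero rows
#'   for a trajectory with no declining segments.
#' @export
classify_trajectory <- function(model, thresholds = nita_thresholds()) {
  bp <- model$breakpoints
  m <- nrow(bp)
  empty <- data.frame(date_before_disturbance = integer(0),
                      date_of_nadir = integer(0), start_value = numeric(0),
                      nadir_value = numeric(0), magnitude = numeric(0),
                      drop_rate = numeric(0), event_class = character(0),
                      recovered = logical(0))
  if (m < 2L) return(empty)
  slope <- diff(bp$value) / (diff(bp$day) / DAYS_PER_YEAR)
  declining <- slope < -thresholds$flat_tol
  if (!any(declining)) return(empty)
  r <- rle(declining)
  seg_end <- cumsum(r$lengths)
  seg_start <- seg_end - r$lengths + 1L
  runs <- which(r$values)
  out <- lapply(runs, function(k) {
    a <- seg_start[k]           # first declining segment index
    b <- seg_end[k]             # last declining segment index
    run_bp <- a:(b + 1L)        # breakpoint indices of the run
    vals <- bp$value[run_bp]
    above <- which(vals >= thresholds$high_ndvi)
    start_i <- run_bp[if (length(above)) max(above) else 1L]
    # qualification (level crossing, rate) uses the run minimum, so that
    # lowering rate_cut can only add disturbances; the reported nadir date
    # is where the rapid decline bottoms out - the last breakpoint below
    # low_ndvi reached by a segment steeper than rate_cut - falling back
    # to the run minimum for slow declines
    min_i <- run_bp[which.min(vals)]
    steep_ends <- a + which(slope[a:b] <= -thresholds$rate_cut)
    below <- run_bp[vals < thresholds$low_ndvi]
    cand <- intersect(steep_ends, below)
    nadir_i <- if (length(cand)) max(cand) else min_i
    v_start <- bp$value[start_i]
    v_nadir <- bp$value[nadir_i]
    crossing_rate <- function(j) {
      yrs <- (bp$day[j] - bp$day[start_i]) / DAYS_PER_YEAR
      if (yrs > 0) (bp$value[start_i] - bp$value[j]) / yrs else Inf
    }
    crosses <- v_start > thresholds$high_ndvi && length(below) > 0L
    # the event's rate is the fastest qualifying crossing: a sharp drop
    # followed by slow drift must not be diluted by the drift
    rate <- if (crosses) max(vapply(below, crossing_rate, numeric(1)))
            else crossing_rate(min_i)
    cls <- if (crosses && rate > thresholds$rate_cut) "disturbance"
           else if (crosses) "decline" else "no_event"
    rec <- FALSE
    if (nadir_i < m) {
      later <- (nadir_i + 1L):m
      up <- slope[later - 1L] > 0
      rec <- any(up & bp$value[later] > thresholds$low_ndvi)
    }
    data.frame(date_before_disturbance = bp$day[start_i],
               date_of_nadir = bp$day[nadir_i],
               start_value = v_start, nadir_value = v_nadir,
               magnitude = v_start - v_nadir, drop_rate = rate,
               event_class = cls, recovered = rec)
  })
  do.call(rbind, out)
}

#' Date of disturbance for a pixel
#'
#' The nadir date of the first (earliest) disturbance event; `NA` when the
#' trajectory contains no disturbance.
#'
#' @param records Data frame from [classify_trajectory()].
#' @return Ordinal day or `NA`.
#' @export
date_of_disturbance <- function(records) {
  d <- records$date_of_nadir[records$event_class == "disturbance"]
  if (length(d) == 0L) return(NA_integer_)
  min(d)
}

#' Cumulative disturbed area by calendar year
#'
#' Counts pixels whose disturbance date falls at or before each calendar
#' year end, times the pixel area. Non-decreasing by construction; pixels
#' with `NA` dates never contribute.
#'
#' @param per_pixel_dates Ordinal-day disturbance dates (NA = undisturbed).
#' @param pixel_area_km2 Area of one pixel in km^2 (0.0009 for 30 m pixels).
#' @param years Calendar years to report (default: range of observed
#'   disturbance years).
#' @return Data frame with `year` and cumulative `area_km2`.
#' @export
cumulative_area <- function(per_pixel_dates, pixel_area_km2 = 0.0009,
                            years = NULL) {
  stopifnot(pixel_area_km2 > 0)
  d <- per_pixel_dates[!is.na(per_pixel_dates)]
  yr <- as.integer(format(as.Date(d, origin = "1970-01-01"), "%Y"))
  if (is.null(years)) {
    years <- if (length(yr)) seq(min(yr), max(yr)) else integer(0)
  }
  area <- vapply(years, function(y) sum(yr <= y) * pixel_area_km2, numeric(1))
  data.frame(year = years, area_km2 = area)
}

#' Correlation of annual disturbance rate with production
#'
#' Pearson correlation between an annual disturbed-area series and an
#' annual production series. When `cumulative = TRUE` the first series is
#' first differenced (rates from a cumulative-area series).
#'
#' @param yearly_disturbed_km2 Annual disturbed area (rates, or cumulative
#'   with `cumulative = TRUE`).
#' @param yearly_production_tons Annual production, same length after any
#'   differencing.
#' @param cumulative Difference the area series first?
#' @return Pearson's r.
#' @export
annual_rate_correlation <- function(yearly_disturbed_km2,
                                    yearly_production_tons,
                                    cumulative = FALSE) {
  a <- yearly_disturbed_km2
  if (cumulative) a <- diff(a)
  b <- yearly_production_tons
  if (length(a) != length(b)) stop("series lengths differ")
  if (length(a) < 3L) stop("need at least 3 years")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero variance in a series; correlation undefined")
  stats::cor(a, b)
}
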