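# The NITA fitter: robust percentile knots, bail-out gate, breakpoint
# insertion at maximum filtered orthogonal error ("build"), and greedy
# backward elimination under a lognormal-likelihood BIC ("subtract").

DIST_FLOOR <- 1e-6
SIGMA_FLOOR <- 1e-6

#' NITA tuning parameters
#'
#' @param prctile Percentile in \[0, 100\] that knot values track; 50 fits
#'   the median of the data, higher values fit an upper envelope (useful
#'   when residual cloud contamination skews the index downward).
#' @param bail_thresh Positive ratio. Breakpoints are only added when the
#'   initial linear fit's mean orthogonal error exceeds `bail_thresh` times
#'   the series noise; otherwise a single-segment model is adopted.
#' @param max_segment Maximum number of segments the build stage may reach
#'   (total breakpoints = segments + 1).
#' @param filt_dist Observation-index kernel radius: the error median filter
#'   uses a `2 * filt_dist + 1` kernel and knot windows span +/- `filt_dist`
#'   observations.
#' @param penalty Positive multiplier on the BIC complexity term; larger
#'   values favour simpler models.
#' @param xy_scale Years of date-axis per unit of index value when computing
#'   orthogonal (perpendicular) distances; the date axis is expressed in
#'   years divided by `xy_scale`.
#' @param revisit_days Nominal sensor revisit period in days (16 for
#'   Landsat). Knot windows are capped at `filt_dist * revisit_days` on
#'   either side of the candidate date so that a window never straddles a
#'   multi-month cloud gap.
#' @return An object of class `nita_params`.
#' @seealso [nita_params_study()] for the parameter set used for tropical
#'   forest disturbance mapping under heavy cloud cover.
#' @export
nita_params <- function(prctile = 50, bail_thresh = 1, max_segment = 10,
                        filt_dist = 3, penalty = 1, xy_scale = 1,
                        revisit_days = 16) {
  stopifnot(prctile >= 0, prctile <= 100, bail_thresh > 0,
            max_segment >= 1, filt_dist >= 1, penalty > 0, xy_scale > 0,
            revisit_days > 0)
  structure(list(prctile = prctile, bail_thresh = bail_thresh,
                 max_segment = as.integer(max_segment),
                 filt_dist = as.integer(filt_dist),
                 penalty = penalty, xy_scale = xy_scale,
                 revisit_days = revisit_days),
            class = "nita_params")
}

#' Study parameter set for cloud-heavy disturbance mapping
#'
#' `prctile = 90` (track the upper envelope through remnant cloud noise),
#' `filt_dist = 3`, `bail_thresh = 2`, `penalty = 4`; other fields at their
#' defaults.
#' @return An object of class `nita_params`.
#' @export
nita_params_study <- function() {
  nita_params(prctile = 90, bail_thresh = 2, max_segment = 10,
              filt_dist = 3, penalty = 4)
}

#' @export
print.nita_params <- function(x, ...) {
  cat(sprintf(
    "nita_params: prctile=%g bail_thresh=%g max_segment=%d filt_dist=%d penalty=%g xy_scale=%g\n",
    x$prctile, x$bail_thresh, x$max_segment, x$filt_dist, x$penalty,
    x$xy_scale))
  invisible(x)
}

# linear-interpolation (type 7) percentile; the single definition used
# package-wide
pctl <- function(x, p) stats::quantile(x, p / 100, type = 7, names = FALSE)

#' Windowed percentile knot value
#'
#' The value assigned to a breakpoint placed at an observation date: the
#' `prctile`-th percentile (linear-interpolation definition) of the
#' observed values in a window of up to +/- `filt_dist` observation
#' indices around `center_index`, additionally capped at
#' `filt_dist * revisit_days` days on either side so that the window never
#' reaches across a long cloud gap (the center and its immediate index
#' neighbours are always retained). When the window is exactly piecewise
#' linear about the center - i.e. a noiseless series - the observed center
#' value is already the exact vertex value and is returned directly; the
#' window percentile is the robust estimator for noisy windows.
#'
#' @param series A `pixel_series` (valid observations only; see
#'   [drop_invalid()]).
#' @param center_index 1-based observation index of the window center.
#' @param prctile Percentile in \[0, 100\].
#' @param filt_dist Window radius in observation indices.
#' @param revisit_days Nominal revisit period used for the time cap.
#' @return Spectral-index value.
#' @export
knot_value <- function(series, center_index, prctile, filt_dist,
                       revisit_days = 16) {
  n <- length(series$day)
  stopifnot(center_index >= 1, center_index <= n)
  idx <- max(1L, center_index - filt_dist):min(n, center_index + filt_dist)
  # exactness escape judged on the full index window; the percentile below
  # uses the time-capped window
  if (piecewise_collinear(series$day[idx], series$value[idx],
                          match(center_index, idx)))
    return(series$value[center_index])
  near <- abs(series$day[idx] - series$day[center_index]) <=
    filt_dist * revisit_days
  near[idx >= center_index - 1L & idx <= center_index + 1L] <- TRUE
  pctl(series$value[idx[near]], prctile)
}

# is the window exactly linear on each side of the center (to 1e-9)?
# Requires at least three points on one side: an exactly collinear triple
# has probability zero under noise, so the escape can only fire on
# noiseless data.
piecewise_collinear <- function(x, y, ci) {
  m <- length(x)
  if (max(ci, m - ci + 1L) < 3L) return(FALSE)
  lin <- function(ii) {
    k <- length(ii)
    if (k <= 2L) return(TRUE)
    s <- (y[ii[k]] - y[ii[1L]]) / (x[ii[k]] - x[ii[1L]])
    all(abs(y[ii] - (y[ii[1L]] + s * (x[ii] - x[ii[1L]]))) < 1e-9)
  }
  lin(seq_len(ci)) && lin(ci:m)
}

#' Orthogonal distances from observations to a piecewise-linear model
#'
#' Perpendicular distance from each observation to the nearest segment of
#' the breakpoint polyline, computed in a rescaled plane where the date axis
#' is in years divided by `xy_scale` and the value axis is in index units.
#'
#' @param model A `nita_model` (or any list with a `breakpoints` data frame
#'   of `day`, `value`).
#' @param series A `pixel_series` spanned by the model (valid observations).
#' @param xy_scale Axis scaling; defaults to the model's fitted value.
#' @return Non-negative numeric vector, one entry per observation.
#' @export
orthogonal_distances <- function(model, series, xy_scale = NULL) {
  if (is.null(xy_scale)) xy_scale <- model$params$xy_scale
  if (is.null(xy_scale)) xy_scale <- 1
  polyline_distances(model$breakpoints$day, model$breakpoints$value,
                     series$day, series$value, xy_scale)
}

# vectorized point-to-polyline distance in the scaled plane
polyline_distances <- function(bday, bval, day, val, xy_scale) {
  px <- day / DAYS_PER_YEAR / xy_scale
  py <- val
  vx <- bday / DAYS_PER_YEAR / xy_scale
  vy <- bval
  best <- rep(Inf, length(px))
  for (j in seq_len(length(vx) - 1L)) {
    dx <- vx[j + 1L] - vx[j]
    dy <- vy[j + 1L] - vy[j]
    l2 <- dx * dx + dy * dy
    if (l2 == 0) {
      ex <- px - vx[j]
      ey <- py - vy[j]
    } else {
      tt <- pmin(1, pmax(0, ((px - vx[j]) * dx + (py - vy[j]) * dy) / l2))
      ex <- px - vx[j] - tt * dx
      ey <- py - vy[j] - tt * dy
    }
    best <- pmin(best, ex * ex + ey * ey)
  }
  sqrt(best)
}

# running median with kernel 2*filt_dist+1; the window shrinks
# symmetrically at the series ends. Kernels longer than the series degrade
# gracefully (with a warning) to the largest odd width that fits.
median_filter <- function(x, filt_dist) {
  n <- length(x)
  k <- 2L * filt_dist + 1L
  if (k > n) {
    warning("filter kernel longer than series; truncating")
    k <- if (n %% 2L == 1L) n else n - 1L
  }
  if (k <= 1L) return(x)
  as.numeric(stats::runmed(x, k, endrule = "median"))
}

new_nita_model <- function(bday, bval, series, params, noise, bailed = FALSE) {
  d <- polyline_distances(bday, bval, series$day, series$value,
                          params$xy_scale)
  ll <- lognormal_loglik(d)
  segs <- length(bday) - 1L
  structure(list(
    breakpoints = data.frame(day = as.integer(bday), value = bval),
    segments = segs,
    distances = d,
    noise = noise,
    loglik = ll,
    n_obs = length(series$day),
    bic = nita_bic(ll, segs, length(series$day), params$penalty),
    params = params,
    bailed = bailed), class = "nita_model")
}

#' @export
print.nita_model <- function(x, ...) {
  cat(sprintf(
    "nita_model: %d segment(s), %d observations, noise %.4g, BIC %.2f%s\n",
    x$segments, x$n_obs, x$noise, x$bic,
    if (isTRUE(x$bailed)) " (bail-out)" else ""))
  bp <- x$breakpoints
  cat(sprintf("  breakpoints: %s\n",
              paste(sprintf("(%s, %.3f)",
                            as.Date(bp$day, origin = "1970-01-01"), bp$value),
                    collapse = " ")))
  invisible(x)
}

#' Evaluate a fitted trajectory at arbitrary dates
#'
#' Linear interpolation between breakpoints; exact at breakpoint dates.
#' Dates outside the model span are an error.
#'
#' @param object A `nita_model`.
#' @param day Ordinal days (or `Date`s) at which to evaluate.
#' @param ... Unused.
#' @return Interpolated spectral-index values.
#' @export
predict.nita_model <- function(object, day, ...) {
  if (inherits(day, "Date")) day <- as.integer(day)
  bp <- object$breakpoints
  if (any(day < bp$day[1L] | day > bp$day[nrow(bp)]))
    stop("date outside model span")
  stats::approx(bp$day, bp$value, xout = day, method = "linear")$y
}

#' Initial single-segment fit
#'
#' Two breakpoints at the first and last observation dates, with values
#' from [knot_value()] at the end windows (robust to outliers there, and
#' exact on a noiseless locally linear series).
#'
#' @param series A `pixel_series` with >= 2 valid observations (invalid
#'   observations are dropped).
#' @param params A [nita_params()] object.
#' @return A single-segment `nita_model`.
#' @export
initial_fit <- function(series, params = nita_params()) {
  s <- drop_invalid(series)
  n <- length(s$day)
  if (n < 2L) stop("initial_fit needs at least 2 valid observations")
  noise <- estimate_noise(s)
  if (n == 2L)  # the line through both points is the only sensible fit
    return(new_nita_model(s$day, s$value, s, params, noise))
  # endpoint windows are never at risk of straddling an interior corner,
  # so the full index window (no time cap) gives the more robust value
  v0 <- knot_value(s, 1L, params$prctile, params$filt_dist, Inf)
  v1 <- knot_value(s, n, params$prctile, params$filt_dist, Inf)
  new_nita_model(c(s$day[1L], s$day[n]), c(v0, v1), s, params, noise)
}

#' Bail-out test for the single-segment fit
#'
#' Compares the ratio of the initial fit's error (mean orthogonal distance)
#' to the series noise against `bail_thresh`. If the threshold is not
#' exceeded (low error and/or high noise) the single-segment model is
#' adopted and no breakpoints are added. A zero-noise series bails only
#' when the fit error is also zero.
#'
#' @param model A single-segment `nita_model` from [initial_fit()].
#' @param noise Non-negative noise scalar from [estimate_noise()].
#' @param bail_thresh Positive threshold ratio.
#' @return `TRUE` to stop with the single-segment model.
#' @export
bail_check <- function(model, noise, bail_thresh) {
  fit_error <- mean(model$distances)
  if (noise == 0) return(fit_error < 1e-12)
  (fit_error / noise) <= bail_thresh
}

#' Lognormal log-likelihood of orthogonal distances
#'
#' Distances are floored at 1e-6; mu and sigma are the maximum-likelihood
#' (population) mean and SD of the log-distances, with sigma floored at
#' 1e-6 to keep the value finite for degenerate spreads. Returns the sum of
#' lognormal log-densities at the distances.
#'
#' @param distances Non-negative numeric vector (non-empty).
#' @return Log-likelihood scalar.
#' @export
lognormal_loglik <- function(distances) {
  stopifnot(length(distances) >= 1L)
  d <- pmax(distances, DIST_FLOOR)
  ld <- log(d)
  mu <- mean(ld)
  sigma <- max(sqrt(mean((ld - mu)^2)), SIGMA_FLOOR)
  sum(stats::dlnorm(d, meanlog = mu, sdlog = sigma, log = TRUE))
}

#' Bayesian Information Criterion for a piecewise fit
#'
#' `BIC = penalty * segments * log(n_obs) - 2 * loglik`. The `penalty`
#' multiplier scales only the complexity term; models with lower BIC are
#' preferred.
#'
#' @param loglik Log-likelihood value.
#' @param segments Number of model segments.
#' @param n_obs Number of observations (>= 1).
#' @param penalty Positive complexity multiplier.
#' @return BIC scalar.
#' @export
nita_bic <- function(loglik, segments, n_obs, penalty) {
  stopifnot(n_obs >= 1)
  penalty * segments * log(n_obs) - 2 * loglik
}

#' NITA build: forward breakpoint insertion
#'
#' Starting from [initial_fit()], repeatedly (i) median-filter the
#' per-observation orthogonal distances with a `2 * filt_dist + 1` kernel,
#' (ii) pick the observation date of maximum filtered error among dates not
#' already breakpoints (ties: earliest date), and (iii) insert a breakpoint
#' there with value [knot_value()] at that index. Stops at `max_segment`
#' segments or when no eligible candidate remains.
#'
#' @param series A `pixel_series` with >= 3 valid observations.
#' @param params A [nita_params()] object.
#' @return A `nita_model` with up to `max_segment` segments.
#' @export
nita_build <- function(series, params = nita_params()) {
  s <- drop_invalid(series)
  if (length(s$day) < 3L) stop("nita_build needs at least 3 valid observations")
  model <- initial_fit(s, params)
  build_from(model, s, params)
}

# insertion loop shared by nita_build and nita_fit (skips refitting the
# initial model)
build_from <- function(model, s, params) {
  n <- length(s$day)
  while (model$segments < params$max_segment) {
    filt <- median_filter(model$distances, params$filt_dist)
    eligible <- !(s$day %in% model$breakpoints$day)
    if (!any(eligible)) break
    filt[!eligible] <- -Inf
    i <- which.max(filt)          # first index on ties -> earliest date
    # the filtered profile plateaus around a corner; within the vetted
    # +/- filt_dist neighborhood the raw error pins the exact date
    nb <- max(1L, i - params$filt_dist):min(n, i + params$filt_dist)
    nb <- nb[eligible[nb]]
    i <- nb[which.max(model$distances[nb])]
    newday <- s$day[i]
    newval <- knot_value(s, i, params$prctile, params$filt_dist,
                         params$revisit_days)
    bday <- c(model$breakpoints$day, newday)
    bval <- c(model$breakpoints$value, newval)
    o <- order(bday)
    model <- new_nita_model(bday[o], bval[o], s, params, model$noise)
  }
  model
}

#' NITA subtract: greedy backward elimination of breakpoints
#'
#' At each round, the BIC of the model with each single interior breakpoint
#' removed is evaluated (surviving breakpoint values are unchanged;
#' distances are recomputed against the re-interpolated polyline). The best
#' removal is accepted if it strictly lowers the BIC; otherwise elimination
#' stops. Endpoints are never removed.
#'
#' @param model A `nita_model` with >= 2 breakpoints.
#' @param series The `pixel_series` the model was fitted to.
#' @param params A [nita_params()] object.
#' @return A `nita_model` with final distances, log-likelihood and BIC.
#' @export
nita_subtract <- function(model, series, params = model$params) {
  s <- drop_invalid(series)
  bday <- model$breakpoints$day
  bval <- model$breakpoints$value
  cur <- model
  repeat {
    m <- nrow(cur$breakpoints)
    if (m <= 2L) break
    best_bic <- cur$bic
    best <- NULL
    for (j in 2:(m - 1L)) {
      cand <- new_nita_model(cur$breakpoints$day[-j],
                             cur$breakpoints$value[-j],
                             s, params, cur$noise)
      if (cand$bic < best_bic) {
        best_bic <- cand$bic
        best <- cand
      }
    }
    if (is.null(best)) break
    cur <- best
  }
  cur
}

#' Fit one pixel with NITA
#'
#' The full per-pixel pipeline: drop invalid observations, estimate noise,
#' fit the initial single segment, bail out if the error/noise ratio is
#' below `bail_thresh`, otherwise run the build and subtract stages.
#' Deterministic for fixed input and parameters.
#'
#' @param series A `pixel_series` with >= 2 valid observations.
#' @param params A [nita_params()] object.
#' @return A `nita_model`.
#' @examples
#' days <- year_to_day(seq(1990, 2000, by = 0.1))
#' ps <- pixel_series(days, rep(0.8, length(days)))
#' nita_fit(ps)  # single flat segment
#' @export
nita_fit <- function(series, params = nita_params()) {
  s <- drop_invalid(series)
  n <- length(s$day)
  if (n < 2L) stop("nita_fit needs at least 2 valid observations")
  model <- initial_fit(s, params)
  if (n < 3L || bail_check(model, model$noise, params$bail_thresh)) {
    model$bailed <- TRUE
    return(model)
  }
  built <- build_from(model, s, params)
  nita_subtract(built, s, params)
}

#' Write a fitted model to delimited text
#'
#' Header lines (`# segments`, `# bic`, `# noise`) followed by one
#' breakpoint per line (`ordinal_day value`).
#'
#' @param model A `nita_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_nita_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# segments %d", model$segments),
               sprintf("# bic %.17g", model$bic),
               sprintf("# noise %.17g", model$noise),
               "ordinal_day value"), con)
  utils::write.table(model$breakpoints, con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a model written by [write_nita_model()]
#'
#' @param path Input file path.
#' @return A list with `breakpoints` (data frame of `day`, `value`),
#'   `segments`, `bic`, `noise`; usable by [predict.nita_model()] and
#'   [classify_trajectory()].
#' @export
read_nita_model <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  get <- function(key) as.numeric(sub(sprintf("^# %s ", key), "",
                                      hdr[startsWith(hdr, sprintf("# %s", key))]))
  d <- utils::read.table(text = lines[!startsWith(lines, "#")], header = TRUE)
  structure(list(breakpoints = data.frame(day = as.integer(d$ordinal_day),
                                          value = d$value),
                 segments = as.integer(get("segments")),
                 bic = get("bic"), noise = get("noise")),
            class = "nita_model")
}
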