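# Simulation-based accuracy assessment: idealized trajectory library,
# autocorrelated cloud-gap model, contamination-aware noise model,
# replicate generation, fit-quality metrics and parameter sweeps.

#' Deterministic Landsat-like acquisition calendar
#'
#' A fixed set of acquisition dates emulating a single-path Landsat
#' archive: the 16-day revisit grid over 1987-2014, thinned to `n_dates`
#' archived scenes by a run-structured (Markov) retention pattern - scenes
#' are archived in short consecutive runs (16-day spacing within a run,
#' mean run length `mean_run`) separated by longer losses, as in a real
#' archive. The pattern is drawn from a fixed internal stream (the first
#' stream yielding exactly `n_dates` scenes), so the calendar is
#' deterministic and acts as a fixed study condition across seeds.
#'
#' @param n_dates Number of scene dates (default 199).
#' @param start,end Date bounds of the record.
#' @param mean_run Mean archived-run length in consecutive 16-day slots.
#' @return Integer ordinal days, strictly increasing.
#' @export
landsat_calendar <- function(n_dates = 199, start = as.Date("1987-01-03"),
                             end = as.Date("2014-12-28"), mean_run = 2) {
  grid <- seq(as.integer(start), as.integer(end), by = 16L)
  n <- length(grid)
  frac <- n_dates / n
  stopifnot(frac > 0, frac < 1)
  p_kk <- 1 - 1 / mean_run
  p_gk <- frac / (1 - frac) * (1 - p_kk)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  for (s in seq_len(100000L)) {
    set.seed(s)
    u <- stats::runif(n)
    keep <- logical(n)
    keep[1] <- u[1] < frac
    for (k in 2:n) keep[k] <- u[k] < (if (keep[k - 1]) p_kk else p_gk)
    if (sum(keep) == n_dates) return(as.integer(grid[keep]))
  }
  stop("could not realize the requested calendar")
}

snap_to <- function(day, calendar) calendar[which.min(abs(calendar - day))]

#' Idealized trajectory library
#'
#' Reconstructs a library of piecewise-linear "truth" trajectories covering
#' the strata of a riverine mining-disturbance landscape: stable forest
#' (1 segment), protracted urbanization decline (2), single inundation with
#' no recovery (3), inundation with ongoing regrowth (4) and braided-river
#' disturbance/recovery dynamics (5). Vertex dates are snapped to the
#' acquisition calendar and disturbance onsets fall uniformly in 1990-2006.
#' All shapes are piecewise monotone with stationary end states, matching
#' typical delineations from real pixel histories.
#'
#' @param n Library size (default 100).
#' @param composition Counts of 1..5-segment trajectories; the default
#'   `c(39, 11, 35, 11, 4)` yields the 3900/1100/3500/1100/400 pixel split
#'   under 10 x 10 replication. Must sum to `n`.
#' @param calendar Acquisition calendar ([landsat_calendar()]).
#' @return A list of `ideal_trajectory` objects, each with `day`, `value`
#'   (vertex polyline), `n_segments`, `stratum` and class
#'   `ideal_trajectory`.
#' @export
make_trajectory_library <- function(n = 100,
                                    composition = c(39, 11, 35, 11, 4),
                                    calendar = landsat_calendar()) {
  if (sum(composition) != n)
    stop("composition must sum to the requested library size")
  d0 <- calendar[1]
  d1 <- calendar[length(calendar)]
  yr <- function(y) year_to_day(y)
  traj <- function(day, value, stratum, segs) {
    structure(list(day = as.integer(day), value = value,
                   n_segments = as.integer(segs), stratum = stratum),
              class = "ideal_trajectory")
  }
  # helper: snap a vector of interior days, enforcing >= 2 calendar steps
  # between consecutive vertices and >= 4 steps from the record ends (so
  # every knot window stays inside one monotone stretch)
  snap_interior <- function(days) {
    lo <- 5L
    hi <- length(calendar) - 4L
    idx <- vapply(days, function(d) which.min(abs(calendar - d)), integer(1))
    idx <- pmin(pmax(idx, lo), hi)
    for (k in seq_along(idx)[-1]) idx[k] <- max(idx[k], idx[k - 1] + 2L)
    idx <- pmin(idx, hi)
    calendar[idx]
  }
  lib <- vector("list", n)
  i <- 0L
  for (s in seq_along(composition)) {
    for (r in seq_len(composition[s])) {
      i <- i + 1L
      lib[[i]] <- switch(s,
        { # 1: stable forest, flat or faint trend
          level <- stats::runif(1, 0.72, 0.88)
          slope <- if (stats::runif(1) < 0.5) 0 else stats::runif(1, -0.004, 0.004)
          half <- (d1 - d0) / 2 / DAYS_PER_YEAR
          traj(c(d0, d1), c(level - slope * half, level + slope * half),
               "stable", 1L)
        },
        { # 2: urbanization-style protracted decline
          pre <- stats::runif(1, 0.75, 0.85)
          knee <- snap_interior(yr(stats::runif(1, 1992, 2006)))
          rate <- stats::runif(1, 0.02, 0.08)
          yrs <- (d1 - knee) / DAYS_PER_YEAR
          endv <- max(0.30, pre - rate * yrs)
          traj(c(d0, knee, d1), c(pre, pre, endv), "urbanization", 2L)
        },
        { # 3: single inundation, no recovery
          pre <- stats::runif(1, 0.74, 0.85)
          post <- stats::runif(1, 0.08, 0.22)
          start <- stats::runif(1, 1990.1, 2004.4)
          dur <- min(stats::runif(1, 0.5, 2.5), 2006.9 - start)
          vdays <- snap_interior(yr(c(start, start + dur)))
          traj(c(d0, vdays, d1), c(pre, pre, post, post), "inundation", 3L)
        },
        { # 4: inundation followed by ongoing regrowth
          pre <- stats::runif(1, 0.74, 0.85)
          post <- stats::runif(1, 0.08, 0.20)
          start <- stats::runif(1, 1990.1, 2000)
          dur <- stats::runif(1, 0.5, 2)
          low <- stats::runif(1, 2, 5)
          vdays <- snap_interior(yr(c(start, start + dur, start + dur + low)))
          endv <- stats::runif(1, 0.45, 0.65)
          traj(c(d0, vdays, d1), c(pre, pre, post, post, endv),
               "inundation_recovery", 4L)
        },
        { # 5: braided-river disturbance and partial recovery
          pre <- stats::runif(1, 0.74, 0.85)
          post <- stats::runif(1, 0.08, 0.20)
          mid <- stats::runif(1, 0.50, 0.72)
          start <- stats::runif(1, 1990.1, 1999)
          dur <- stats::runif(1, 0.5, 1.5)
          low <- stats::runif(1, 1, 3)
          rise <- stats::runif(1, 1, 3)
          vdays <- snap_interior(yr(c(start, start + dur, start + dur + low,
                                      start + dur + low + rise)))
          traj(c(d0, vdays, d1), c(pre, pre, post, post, mid, mid),
               "braided", 5L)
        })
    }
  }
  lib
}

#' @export
print.ideal_trajectory <- function(x, ...) {
  cat(sprintf("ideal_trajectory: %s, %d segment(s)\n", x$stratum,
              x$n_segments))
  invisible(x)
}

# evaluate a truth polyline at arbitrary days
truth_values <- function(truth, day) {
  stats::approx(truth$day, truth$value, xout = day, method = "linear")$y
}

#' Autocorrelated cloud-gap model
#'
#' A two-state Markov chain over the acquisition calendar: each scene date
#' is valid (clear at the pixel) or invalid (cloud/SLC gap). The chain is
#' parameterized by its stationary valid probability (default 0.45,
#' matching the 55% mean scene cloud cover of the study archive) and the
#' mean length of valid runs (default 2 consecutive acquisitions),
#' emulating the temporal autocorrelation of cloud cover.
#'
#' @param valid_frac Stationary valid probability in (0, 1\].
#' @param mean_valid_run Mean valid-run length in acquisitions (>= 1).
#' @return An object of class `gap_model`.
#' @export
gap_model <- function(valid_frac = 0.45, mean_valid_run = 2) {
  stopifnot(valid_frac > 0, valid_frac <= 1, mean_valid_run >= 1)
  p_vv <- if (valid_frac >= 1) 1 else 1 - 1 / mean_valid_run
  p_iv <- if (valid_frac >= 1) 1 else valid_frac / (1 - valid_frac) * (1 - p_vv)
  if (p_iv > 1)
    stop("inconsistent gap model: valid_frac too high for mean_valid_run")
  structure(list(valid_frac = valid_frac, mean_valid_run = mean_valid_run,
                 p_vv = p_vv, p_iv = p_iv), class = "gap_model")
}

#' Sample valid-date subsets from the gap model
#'
#' Runs the Markov chain over the calendar once per requested set. The
#' expected valid fraction equals the stationary probability; identical
#' seeds give identical subsets.
#'
#' @param calendar Integer ordinal days ([landsat_calendar()]).
#' @param gap A [gap_model()] object.
#' @param n_sets Number of independent subsets.
#' @param seed Optional integer seed.
#' @return A list of logical vectors (length of `calendar`), `TRUE` for
#'   valid dates; each subset retains at least 4 dates.
#' @export
sample_valid_dates <- function(calendar, gap = gap_model(), n_sets = 1,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(calendar)
  one <- function() {
    repeat {
      v <- logical(n)
      u <- stats::runif(n)
      v[1] <- u[1] < gap$valid_frac
      for (k in 2:n)
        v[k] <- u[k] < (if (v[k - 1]) gap$p_vv else gap$p_iv)
      if (sum(v) >= 4L) return(v)
    }
  }
  lapply(seq_len(n_sets), function(k) one())
}

#' Observation noise model
#'
#' The default `"contaminated"` kind emulates the data-driven noise of
#' humid-tropics Landsat NDVI: a small clear-sky Gaussian component
#' (`clear_sd`) plus, with probability `contamination`, an exponential
#' downward excursion (remnant cloud/shadow/haze that escapes the mask and
#' depresses NDVI). The excursion mean is solved so the total standard
#' deviation equals `sd` (default 0.2 NDVI). This lower-tail skew is the
#' reason an upper-envelope percentile (`prctile = 90`) is the effective
#' fitting choice. Also available: `"gaussian"` (symmetric, SD `sd`) and
#' `"empirical"` (resampling a user-supplied residual pool).
#'
#' @param kind One of `"contaminated"`, `"gaussian"`, `"empirical"`.
#' @param sd Total noise SD in NDVI units (default 0.2).
#' @param contamination Probability a valid date still carries contamination
#'   (default 0.3).
#' @param clear_sd Clear-sky SD (default 0.015).
#' @param pool Residual pool for `kind = "empirical"`.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(kind = c("contaminated", "gaussian", "empirical"),
                        sd = 0.2, contamination = 0.3, clear_sd = 0.015,
                        pool = NULL) {
  kind <- match.arg(kind)
  stopifnot(sd >= 0)
  drop_mean <- NA_real_
  if (kind == "contaminated") {
    q <- contamination
    v <- sd^2 - clear_sd^2
    if (v <= 0 || q <= 0) stop("sd must exceed clear_sd with contamination > 0")
    drop_mean <- sqrt(v / (q * (2 - q)))
  }
  if (kind == "empirical" && (is.null(pool) || length(pool) < 2L))
    stop("empirical noise needs a residual pool")
  structure(list(kind = kind, sd = sd, contamination = contamination,
                 clear_sd = clear_sd, drop_mean = drop_mean, pool = pool),
            class = "noise_model")
}

draw_noise <- function(noise, n) {
  switch(noise$kind,
         gaussian = stats::rnorm(n, 0, noise$sd),
         contaminated = {
           eps <- stats::rnorm(n, 0, noise$clear_sd)
           hit <- stats::runif(n) < noise$contamination
           eps - hit * stats::rexp(n, rate = 1 / noise$drop_mean)
         },
         empirical = sample(noise$pool, n, replace = TRUE))
}

#' Synthesize one simulated pixel
#'
#' Interpolates the truth trajectory at the sampled valid dates, adds one
#' noise draw, and clips to \[-1, 1\].
#'
#' @param truth An `ideal_trajectory`.
#' @param days Ordinal days (within the truth span) of valid observations.
#' @param noise A [noise_model()] object.
#' @param seed Optional integer seed (recorded on the result).
#' @return A `pixel_series` with attribute `"seed"`.
#' @export
synthesize_pixel <- function(truth, days, noise = noise_model(),
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- truth_values(truth, days) + draw_noise(noise, length(days))
  out <- pixel_series(days, pmin(1, pmax(-1, v)))
  attr(out, "seed") <- seed
  out
}

# classify a truth polyline with the same rules as a fitted model
truth_events <- function(truth, thresholds) {
  classify_trajectory(list(breakpoints = data.frame(day = truth$day,
                                                    value = truth$value)),
                      thresholds)
}

#' Compare fitted models against their originating trajectories
#'
#' Per pixel: the absolute and signed error in the number of segments, the
#' RMSE between the fitted and true trajectories on a daily grid over the
#' common span, and - for pixels whose truth contains a disturbance - the
#' signed and absolute day offsets of the fitted date-before-disturbance
#' and date-of-nadir breakpoints (classified with the standard
#' thresholds). Fits in which no disturbance event is found are counted as
#' misses and excluded from the date means.
#'
#' @param fits List of `nita_model` objects.
#' @param truths List of `ideal_trajectory` objects, aligned one-to-one.
#' @param thresholds A [nita_thresholds()] object.
#' @return A data frame with one row per pixel: `stratum`, `true_segments`,
#'   `fit_segments`, `seg_err` (absolute), `rmse`, `true_start`,
#'   `true_nadir`, `start_err`, `nadir_err` (signed days, NA when not
#'   applicable), `miss` (truth disturbed but fit found no disturbance).
#'   Summarize with [summarize_assessment()].
#' @export
evaluate_fits <- function(fits, truths, thresholds = nita_thresholds()) {
  stopifnot(length(fits) == length(truths))
  rows <- lapply(seq_along(fits), function(i) {
    fit <- fits[[i]]
    truth <- truths[[i]]
    bp <- fit$breakpoints
    grid <- seq(bp$day[1], bp$day[nrow(bp)])
    rmse <- sqrt(mean((predict(fit, grid) - truth_values(truth, grid))^2))
    te <- truth_events(truth, thresholds)
    te <- te[te$event_class == "disturbance", , drop = FALSE]
    start_err <- nadir_err <- NA_real_
    true_start <- true_nadir <- NA_integer_
    miss <- NA
    if (nrow(te) > 0L) {
      true_start <- te$date_before_disturbance[1]
      true_nadir <- te$date_of_nadir[1]
      fe <- classify_trajectory(fit, thresholds)
      fe <- fe[fe$event_class == "disturbance", , drop = FALSE]
      miss <- nrow(fe) == 0L
      if (!miss) {
        start_err <- fe$date_before_disturbance[1] - true_start
        nadir_err <- fe$date_of_nadir[1] - true_nadir
      }
    }
    data.frame(stratum = truth$stratum, true_segments = truth$n_segments,
               fit_segments = fit$segments,
               seg_err = abs(fit$segments - truth$n_segments),
               rmse = rmse, true_start = true_start, true_nadir = true_nadir,
               start_err = start_err, nadir_err = nadir_err, miss = miss)
  })
  do.call(rbind, rows)
}

#' Aggregate an assessment table
#'
#' Means of the per-pixel metrics overall and per stratum: mean absolute
#' segment-count error, mean RMSE, mean absolute and signed (bias) date
#' errors, and the disturbance miss rate.
#'
#' @param tab Data frame from [evaluate_fits()].
#' @return Data frame with one row per stratum plus an `"overall"` row.
#' @export
summarize_assessment <- function(tab) {
  agg <- function(sub, label) {
    data.frame(stratum = label, n = nrow(sub),
               seg_mae = mean(sub$seg_err),
               rmse = mean(sub$rmse),
               start_mae = mean(abs(sub$start_err), na.rm = TRUE),
               nadir_mae = mean(abs(sub$nadir_err), na.rm = TRUE),
               start_bias = mean(sub$start_err, na.rm = TRUE),
               nadir_bias = mean(sub$nadir_err, na.rm = TRUE),
               miss_rate = if (all(is.na(sub$miss))) NA_real_
                           else mean(sub$miss, na.rm = TRUE))
  }
  strata <- unique(tab$stratum)
  rbind(do.call(rbind, lapply(strata,
                              function(s) agg(tab[tab$stratum == s, ], s))),
        agg(tab, "overall"))
}

#' Run a full simulated accuracy assessment
#'
#' For each trajectory in the library, draws `n_date_sets` valid-date
#' subsets from the gap model and `n_noise_sets` noise realizations per
#' date set, fits every simulated pixel with NITA, and evaluates the fits
#' against truth. The default 100 x 10 x 10 design yields 10,000 pixels.
#' All randomness flows through `seed`; sub-seeds for every date set and
#' noise draw are recorded in the returned manifest so any single pixel can
#' be regenerated exactly.
#'
#' @param library Trajectory library ([make_trajectory_library()]).
#' @param params Fitting parameters (default [nita_params_study()]).
#' @param thresholds Classification thresholds.
#' @param n_date_sets,n_noise_sets Replication per trajectory.
#' @param gap A [gap_model()].
#' @param noise A [noise_model()].
#' @param calendar Acquisition calendar.
#' @param seed Integer seed for the whole run.
#' @return A list with `pixels` (the [evaluate_fits()] table, plus
#'   trajectory/date-set/noise-set ids), `summary`
#'   ([summarize_assessment()]) and `manifest` (recorded sub-seeds).
#' @export
run_assessment <- function(library = NULL, params = nita_params_study(),
                           thresholds = nita_thresholds(),
                           n_date_sets = 10, n_noise_sets = 10,
                           gap = gap_model(), noise = noise_model(),
                           calendar = landsat_calendar(), seed = 1) {
  set.seed(seed)
  if (is.null(library)) library <- make_trajectory_library(calendar = calendar)
  n_traj <- length(library)
  date_seeds <- matrix(sample.int(.Machine$integer.max, n_traj * n_date_sets),
                       n_traj, n_date_sets)
  noise_seeds <- array(sample.int(.Machine$integer.max,
                                  n_traj * n_date_sets * n_noise_sets),
                       c(n_traj, n_date_sets, n_noise_sets))
  fits <- vector("list", n_traj * n_date_sets * n_noise_sets)
  truths <- vector("list", length(fits))
  ids <- matrix(0L, length(fits), 3L)
  px <- 0L
  for (ti in seq_len(n_traj)) {
    truth <- library[[ti]]
    for (di in seq_len(n_date_sets)) {
      vmask <- sample_valid_dates(calendar, gap, 1,
                                  seed = date_seeds[ti, di])[[1]]
      days <- calendar[vmask]
      for (ni in seq_len(n_noise_sets)) {
        px <- px + 1L
        sim <- synthesize_pixel(truth, days, noise,
                                seed = noise_seeds[ti, di, ni])
        fits[[px]] <- nita_fit(sim, params)
        truths[[px]] <- truth
        ids[px, ] <- c(ti, di, ni)
      }
    }
  }
  tab <- evaluate_fits(fits, truths, thresholds)
  tab <- cbind(data.frame(trajectory = ids[, 1], date_set = ids[, 2],
                          noise_set = ids[, 3]), tab)
  list(pixels = tab, summary = summarize_assessment(tab),
       manifest = list(seed = seed, date_seeds = date_seeds,
                       noise_seeds = noise_seeds,
                       params = params, gap = gap, noise = noise))
}

#' Parameter sensitivity sweep
#'
#' Runs a (typically reduced-replication) assessment at each row of a
#' parameter grid and collects the overall metrics, exposing the tradeoff
#' between segment-count accuracy and fit precision.
#'
#' @param grid Data frame with any of the columns `bail_thresh`,
#'   `filt_dist`, `penalty` (others taken from `base_params`).
#' @param library Trajectory library (default: the standard library).
#' @param base_params Baseline parameters.
#' @param ... Passed to [run_assessment()] (e.g. `n_date_sets`,
#'   `n_noise_sets`, `seed`).
#' @return The grid with the overall metric columns appended.
#' @export
parameter_sweep <- function(grid, library = NULL,
                            base_params = nita_params_study(), ...) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1)
  if (is.null(library)) library <- make_trajectory_library()
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    p <- base_params
    for (f in intersect(names(grid), c("bail_thresh", "filt_dist", "penalty",
                                       "prctile", "max_segment")))
      p[[f]] <- grid[[f]][g]
    p <- do.call(nita_params, p[c("prctile", "bail_thresh", "max_segment",
                                  "filt_dist", "penalty", "xy_scale")])
    res <- run_assessment(library = library, params = p, ...)
    ov <- res$summary[res$summary$stratum == "overall", ]
    cbind(grid[g, , drop = FALSE], ov[, setdiff(names(ov), "stratum")],
          row.names = NULL)
  })
  do.call(rbind, rows)
}
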