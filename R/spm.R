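# Coastal suspended particulate matter (SPM): single red-band retrieval,
# trident transect geometry, median/90th-percentile aggregation, and the
# impacted-vs-reference outlet comparison.

#' SPM retrieval coefficients
#'
#' Empirical coefficients for the 660 nm center of the Landsat TM/ETM+ red
#' band: `A` = 327.84 g/m^3, `C` = 0.1708 (dimensionless reflectance).
#'
#' @param A Scale coefficient in g/m^3 (> 0).
#' @param C Saturation reflectance (0 < C < 1).
#' @return An object of class `spm_params`.
#' @export
spm_params <- function(A = 327.84, C = 0.1708) {
  stopifnot(A > 0, C > 0, C < 1)
  structure(list(A = A, C = C), class = "spm_params")
}

#' SPM concentration from red-band water-leaving reflectance
#'
#' `SPM = A * rho_w / (1 - rho_w / C)`, positive and increasing on
#' \[0, C). Reflectances at or above `C` (about 17%) are disallowed by the
#' model (the retrieval diverges/turns negative; typically silt or unmasked
#' cloud) and return `NA`. Negative reflectance is an input error.
#'
#' @param rho_w Water-leaving red reflectance in \[0, 1\] (vectorized).
#' @param params A [spm_params()] object.
#' @return SPM concentration in g/m^3; `NA` where the retrieval is invalid.
#' @examples
#' spm_from_reflectance(0.1708 / 2)  # A * C = 55.995
#' @export
spm_from_reflectance <- function(rho_w, params = spm_params()) {
  if (any(rho_w < 0, na.rm = TRUE)) stop("reflectance must be non-negative")
  out <- params$A * rho_w / (1 - rho_w / params$C)
  out[!is.finite(rho_w) | rho_w >= params$C] <- NA_real_
  out
}

#' Build a trident sampling transect
#'
#' Three prongs fan out from a river-outlet origin about a seaward bearing,
#' each sampled at `points_per_prong` evenly spaced points from just off
#' the origin out to `length_km` (the origin itself is not duplicated
#' across prongs). Bearings are compass degrees (0 = +y north, clockwise).
#'
#' @param origin Numeric `c(x, y)` map coordinates in km.
#' @param bearing Central prong bearing, degrees.
#' @param length_km Prong length in km (> 0; the study used 1-15 km).
#' @param points_per_prong Sample points per prong (>= 2; 67 gives the
#'   201-point configuration used at 2 km).
#' @param prong_angles Degree offsets of the three prongs from `bearing`.
#' @return An object of class `trident` with a `points` data frame
#'   (`id`, `prong`, `x`, `y`) and the generating fields.
#' @export
build_trident <- function(origin = c(0, 0), bearing = 180, length_km = 2,
                          points_per_prong = 67,
                          prong_angles = c(-30, 0, 30)) {
  stopifnot(length_km > 0, points_per_prong >= 2, length(prong_angles) == 3)
  dist <- seq_len(points_per_prong) / points_per_prong * length_km
  pts <- do.call(rbind, lapply(seq_along(prong_angles), function(k) {
    theta <- (bearing + prong_angles[k]) * pi / 180
    data.frame(prong = k,
               x = origin[1] + sin(theta) * dist,
               y = origin[2] + cos(theta) * dist)
  }))
  pts <- cbind(id = seq_len(nrow(pts)), pts)
  structure(list(points = pts, origin = origin, bearing = bearing,
                 length_km = length_km, points_per_prong = points_per_prong,
                 prong_angles = prong_angles), class = "trident")
}

#' @export
print.trident <- function(x, ...) {
  cat(sprintf("trident: origin (%g, %g), bearing %g deg, %g km, %d points\n",
              x$origin[1], x$origin[2], x$bearing, x$length_km,
              nrow(x$points)))
  invisible(x)
}

#' Write transect points as simple geometry text
#'
#' One point per line: `id x y`.
#' @param trident A [build_trident()] object (or a `points` data frame).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_transect <- function(trident, path) {
  pts <- if (inherits(trident, "trident")) trident$points else trident
  utils::write.table(pts[, c("id", "x", "y")], path, row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Read transect points written by [write_transect()]
#' @param path Input file path.
#' @return Data frame with `id`, `x`, `y`.
#' @export
read_transect <- function(path) utils::read.table(path, header = TRUE)

#' SPM sample matrix
#'
#' Dates x points matrix of SPM concentrations for one outlet. Negative or
#' non-finite entries are masked invalid (`NA`); retained values are always
#' non-negative.
#'
#' @param values Numeric matrix, rows = image dates, columns = sample
#'   points.
#' @param day Ordinal days (or `Date`s), one per row.
#' @param outlet Outlet label (e.g. `"ADA"` or a reference-outlet id).
#' @return An object of class `spm_samples`.
#' @export
spm_samples <- function(values, day, outlet = "outlet") {
  values <- as.matrix(values)
  if (inherits(day, "Date")) day <- as.integer(day)
  stopifnot(nrow(values) == length(day))
  values[!is.finite(values) | values < 0] <- NA_real_
  structure(list(values = values, day = as.integer(day), outlet = outlet),
            class = "spm_samples")
}

#' Spatial aggregation: per-date median over transect points
#'
#' The SPM concentration for an image date is the median over all valid
#' sample points, which is robust to outliers such as unmasked cloud edges.
#'
#' @param samples An [spm_samples()] object.
#' @param day Optional subset of dates (default: all).
#' @return Data frame with `day` and `spm` (NA for dates with no valid
#'   point).
#' @export
spatial_aggregate <- function(samples, day = samples$day) {
  rows <- match(day, samples$day)
  spm <- vapply(rows, function(r) {
    if (is.na(r)) return(NA_real_)
    v <- samples$values[r, ]
    v <- v[!is.na(v)]
    if (length(v) == 0L) NA_real_ else stats::median(v)
  }, numeric(1))
  data.frame(day = day, spm = spm)
}

#' Temporal aggregation: 90th percentile over a period
#'
#' Aggregates per-date medians with the 90th percentile
#' (linear-interpolation definition), reflecting that in mountain rivers a
#' large share of the annual sediment flux moves in a small number of
#' high-flow days.
#'
#' @param series Data frame with `day` and `spm` (from
#'   [spatial_aggregate()]).
#' @param period Optional `c(first_day, last_day)` ordinal-day window
#'   (inclusive; default: all dates).
#' @param prob Percentile (default 0.90).
#' @return Aggregated g/m^3, or `NA` for an empty period.
#' @export
temporal_aggregate <- function(series, period = NULL, prob = 0.90) {
  v <- series$spm
  if (!is.null(period)) v <- v[series$day >= period[1] & series$day <= period[2]]
  v <- v[!is.na(v)]
  if (length(v) == 0L) return(NA_real_)
  pctl(v, prob * 100)
}

#' Per-year median and interquartile range of SPM samples
#'
#' Pools all valid (date, point) samples within each calendar year;
#' duplicate dates are pooled, not averaged first.
#'
#' @param samples An [spm_samples()] object.
#' @return Data frame with `year`, `n`, `median`, `q25`, `q75`, `iqr`;
#'   years with no valid samples are omitted.
#' @export
yearly_summary <- function(samples) {
  year <- as.integer(format(as.Date(samples$day, origin = "1970-01-01"), "%Y"))
  out <- lapply(sort(unique(year)), function(y) {
    v <- samples$values[year == y, , drop = FALSE]
    v <- v[!is.na(v)]
    if (length(v) == 0L) return(NULL)
    q <- pctl(v, c(25, 50, 75))
    data.frame(year = y, n = length(v), median = q[2], q25 = q[1],
               q75 = q[3], iqr = q[3] - q[1])
  })
  do.call(rbind, out)
}

#' Compare an impacted outlet against reference outlets across a split year
#'
#' Computes per-period 90th-percentile SPM for each group, the percent
#' change `(post - pre) / pre * 100`, a Welch (unequal-variance) two-sample
#' t-test of impacted vs reference per-date values within the post period,
#' and per-year Welch tests where both groups have data.
#'
#' @param ada Data frame with `day`, `spm`: per-date medians at the
#'   impacted (deposition-area) outlet.
#' @param nonada Same for the pooled reference outlets.
#' @param split_year First calendar year of the post period (default 1998).
#' @return A list with `p90` (per group and period), `pct_change`,
#'   `post_test` (Welch t on post-period values) and `yearly` (per-year
#'   statistics and p-values).
#' @export
compare_outlets <- function(ada, nonada, split_year = 1998) {
  split_day <- as.integer(as.Date(sprintf("%d-01-01", split_year)))
  grp <- function(df, post) {
    v <- df$spm[if (post) df$day >= split_day else df$day < split_day]
    v[!is.na(v)]
  }
  a_pre <- grp(ada, FALSE); a_post <- grp(ada, TRUE)
  n_pre <- grp(nonada, FALSE); n_post <- grp(nonada, TRUE)
  p90 <- function(v) if (length(v)) pctl(v, 90) else NA_real_
  pchg <- function(pre, post) {
    if (is.na(pre) || is.na(post) || pre == 0) return(NA_real_)
    (post - pre) / pre * 100
  }
  p90s <- data.frame(group = c("ada", "nonada"),
                     pre = c(p90(a_pre), p90(n_pre)),
                     post = c(p90(a_post), p90(n_post)))
  welch <- function(a, b) {
    if (length(a) < 2L || length(b) < 2L) return(NULL)
    tryCatch(stats::t.test(a, b, var.equal = FALSE),
             error = function(e) NULL)   # zero-variance samples
  }
  test <- welch(a_post, n_post)
  years <- intersect(year_of(ada$day), year_of(nonada$day))
  yearly <- do.call(rbind, lapply(sort(years), function(y) {
    av <- ada$spm[year_of(ada$day) == y]; av <- av[!is.na(av)]
    nv <- nonada$spm[year_of(nonada$day) == y]; nv <- nv[!is.na(nv)]
    tt <- welch(av, nv)
    if (is.null(tt)) return(NULL)
    data.frame(year = y, t = unname(tt$statistic), p = tt$p.value,
               ada_mean = mean(av), nonada_mean = mean(nv))
  }))
  list(p90 = p90s,
       pct_change = data.frame(group = c("ada", "nonada"),
                               pct = c(pchg(p90s$pre[1], p90s$post[1]),
                                       pchg(p90s$pre[2], p90s$post[2]))),
       post_test = test,
       yearly = yearly)
}

year_of <- function(day) as.integer(format(as.Date(day, origin = "1970-01-01"), "%Y"))
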