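# Shared fixtures: small deterministic series and trajectories built in code.

# a pixel series lying exactly on a piecewise-linear polyline, sampled at
# `days`
polyline_series <- function(vertex_day, vertex_value, days) {
  pixel_series(days, approx(vertex_day, vertex_value, xout = days)$y)
}

# flat + steep drop + flat ("single inundation") truth over a calendar
inundation_truth <- function(calendar, pre = 0.8, post = 0.15,
                             start_idx = 80, nadir_idx = 90) {
  structure(list(day = as.integer(c(calendar[1], calendar[start_idx],
                                    calendar[nadir_idx],
                                    calendar[length(calendar)])),
                 value = c(pre, pre, post, post),
                 n_segments = 3L, stratum = "inundation"),
            class = "ideal_trajectory")
}

# minimal model-like object for classification tests
bp_model <- function(day, value) {
  structure(list(breakpoints = data.frame(day = as.integer(day),
                                          value = value),
                 segments = length(day) - 1L),
            class = "nita_model")
}

# years -> ordinal days shorthand for readable test trajectories
yd <- function(y) year_to_day(y)

# independent oracle: minimum BIC over all subsets of interior breakpoints
# of a built model (breakpoint values fixed, distances recomputed)
exhaustive_subset_bic <- function(built, s, params) {
  bp <- built$breakpoints
  m <- nrow(bp)
  interior <- seq_len(m)[-c(1, m)]
  best <- Inf
  for (mask in 0:(2^length(interior) - 1)) {
    drop <- interior[bitwAnd(bitwShiftL(1, seq_along(interior) - 1),
                             mask) > 0]
    keep <- setdiff(seq_len(m), drop)
    d <- nita:::polyline_distances(bp$day[keep], bp$value[keep],
                                   s$day, s$value, params$xy_scale)
    ll <- lognormal_loglik(d)
    best <- min(best, nita_bic(ll, length(keep) - 1L, length(s$day),
                               params$penalty))
  }
  best
}
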