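test_that("parameter constructors enforce ranges and defaults", {
  p <- nita_params()
  expect_equal(p$prctile, 50)
  expect_equal(p$bail_thresh, 1)
  expect_equal(p$max_segment, 10L)
  expect_equal(p$filt_dist, 3L)
  expect_equal(p$penalty, 1)
  s <- nita_params_study()
  expect_equal(s$prctile, 90)
  expect_equal(s$bail_thresh, 2)
  expect_equal(s$filt_dist, 3L)
  expect_equal(s$penalty, 4)
  expect_error(nita_params(prctile = 101))
  expect_error(nita_params(bail_thresh = 0))
  expect_error(nita_params(penalty = -1))
})

test_that("knot_value reproduces windowed percentiles", {
  const <- pixel_series(seq(0, 160, by = 16), rep(0.7, 11))
  expect_equal(knot_value(const, 5, 90, 3), 0.7)
  # explicit window {0.2, 0.4, 0.6}: median 0.4, maximum 0.6
  w <- pixel_series(c(0, 16, 32), c(0.2, 0.6, 0.4))
  expect_equal(knot_value(w, 2, 50, 1), 0.4)
  expect_equal(knot_value(w, 2, 100, 1), 0.6)
  # noisy flat window with one low outlier at prctile 90 resists the outlier
  out <- pixel_series(seq(0, 96, by = 16), c(0.8, 0.8, 0.8, 0.1, 0.8, 0.8, 0.8))
  expect_gte(knot_value(out, 4, 90, 3), 0.8 - 1e-9)
})

test_that("interpolation is exact at breakpoints and linear between them", {
  m <- bp_model(c(0, 100, 200), c(0.8, 0.8, 0.2))
  expect_equal(predict(m, c(0, 100, 200)), c(0.8, 0.8, 0.2))
  expect_equal(predict(m, 150), 0.5)
  m2 <- bp_model(c(0, 100), c(0, 1))
  expect_equal(predict(m2, 50), 0.5)
  expect_error(predict(m, 201), "span")
})

test_that("orthogonal distances match plane geometry", {
  # point on the polyline
  s_on <- pixel_series(c(0, 100, 200), c(0.1, 0.3, 0.5))
  m <- bp_model(c(0, 200), c(0.1, 0.5))
  expect_equal(orthogonal_distances(m, s_on, xy_scale = 1),
               rep(0, 3), tolerance = 1e-12)
  # horizontal segment, vertical offset 0.2 at any scale
  mh <- bp_model(c(0, 400), c(0.5, 0.5))
  sh <- pixel_series(200, 0.7)
  expect_equal(orthogonal_distances(mh, sh, xy_scale = 1), 0.2)
  expect_equal(orthogonal_distances(mh, sh, xy_scale = 7), 0.2)
  # 45-degree segment in the scaled plane: vertical 0.2 -> 0.2 / sqrt(2)
  m45 <- bp_model(c(0, 365), c(0, 365 / 365.25))
  s45 <- pixel_series(182, 182 / 365.25 + 0.2)
  expect_equal(orthogonal_distances(m45, s45, xy_scale = 1), 0.2 / sqrt(2),
               tolerance = 1e-3)
})

test_that("initial fit passes through noiseless lines and resists end outliers", {
  days <- seq(0, 3650, by = 73)
  line <- pixel_series(days, 0.2 + 0.0001 * days)
  f <- initial_fit(line, nita_params())
  expect_lt(max(orthogonal_distances(f, line)), 1e-9)
  # two-point series: model passes through both points
  two <- pixel_series(c(0, 100), c(0.3, 0.9))
  f2 <- initial_fit(two, nita_params())
  expect_equal(f2$breakpoints$value, c(0.3, 0.9))
  # flat series with a low outlier in the end window, prctile 90
  v <- rep(0.8, 30)
  v[29] <- 0.1
  fl <- initial_fit(pixel_series(seq_along(v) * 16, v),
                    nita_params(prctile = 90))
  expect_gte(fl$breakpoints$value[2], 0.8 - 1e-9)
})

test_that("bail-out compares the error/noise ratio against the threshold", {
  m <- list(distances = rep(0, 10))
  expect_true(bail_check(m, noise = 0.3, bail_thresh = 1))
  m$distances <- rep(0.4, 10)
  expect_false(bail_check(m, noise = 0.1, bail_thresh = 2))  # ratio 4
  m$distances <- rep(0.1, 10)
  expect_true(bail_check(m, noise = 0.1, bail_thresh = 1))   # boundary ratio 1
  # zero noise bails only on a perfect fit
  expect_false(bail_check(m, noise = 0, bail_thresh = 5))
  m$distances <- rep(0, 4)
  expect_true(bail_check(m, noise = 0, bail_thresh = 5))
  # noise -> Inf always bails
  m$distances <- rep(10, 4)
  expect_true(bail_check(m, noise = 1e12, bail_thresh = 0.01))
})

test_that("lognormal log-likelihood matches the closed form", {
  # distances {e^0, e^2}: mu = 1, sigma = 1 (population SD)
  d <- c(1, exp(2))
  mu <- 1
  sigma <- 1
  expected <- sum(-log(d * sigma * sqrt(2 * pi)) -
                    (log(d) - mu)^2 / (2 * sigma^2))
  expect_equal(lognormal_loglik(d), expected)
  # degenerate spread is floored, stays finite
  expect_true(is.finite(lognormal_loglik(rep(0.05, 20))))
  expect_true(is.finite(lognormal_loglik(rep(0, 5))))
})

test_that("BIC composition and penalty linearity", {
  expect_equal(nita_bic(0, 1, 1, 1), 0)
  expect_equal(nita_bic(-10, 3, 100, 4), 4 * 3 * log(100) + 20)
  b1 <- nita_bic(-5, 4, 50, 1)
  b2 <- nita_bic(-5, 4, 50, 2)
  expect_equal(b2 - b1, 4 * log(50))
})

test_that("build recovers noiseless vertices and respects max_segment", {
  days <- seq(0, 5000, by = 50)
  truth_d <- c(0, 2000, 2500, 5000)
  truth_v <- c(0.8, 0.8, 0.15, 0.15)
  s <- polyline_series(truth_d, truth_v, days)
  built <- nita_build(s, nita_params(prctile = 50, max_segment = 3))
  # first inserted breakpoints land on (or adjacent to) the true vertices
  expect_true(all(vapply(c(2000, 2500), function(d)
    min(abs(built$breakpoints$day - d)) <= 3 * 50, logical(1))))
  # straight line: any number of inserted breakpoints keeps distances ~ 0
  line <- pixel_series(days, 0.2 + days * 1e-4)
  bl <- nita_build(line, nita_params(max_segment = 6))
  expect_lt(max(bl$distances), 1e-9)
  # max_segment = 1 returns the initial fit
  b1 <- nita_build(s, nita_params(max_segment = 1))
  expect_equal(nrow(b1$breakpoints), 2L)
  expect_equal(b1$breakpoints, initial_fit(s, nita_params())$breakpoints)
})

test_that("subtract only removes interior breakpoints and lowers BIC", {
  days <- seq(0, 5000, by = 50)
  s <- polyline_series(c(0, 2000, 2500, 5000), c(0.8, 0.8, 0.15, 0.15), days)
  p <- nita_params(prctile = 50, max_segment = 6)
  built <- nita_build(s, p)
  sub <- nita_subtract(built, s, p)
  expect_lte(sub$bic, built$bic)
  expect_equal(sub$segments, 3L)
  expect_equal(sub$breakpoints$day[c(1, nrow(sub$breakpoints))],
               built$breakpoints$day[c(1, nrow(built$breakpoints))])
  # two-breakpoint model is returned unchanged
  init <- initial_fit(s, p)
  expect_equal(nita_subtract(init, s, p)$breakpoints, init$breakpoints)
  # huge penalty on pure noise collapses to a single segment
  set.seed(7)
  noisy <- pixel_series(days, rnorm(length(days), 0.5, 0.2))
  pbig <- nita_params(max_segment = 6, penalty = 1000)
  collapsed <- nita_subtract(nita_build(noisy, pbig), noisy, pbig)
  expect_equal(collapsed$segments, 1L)
})

test_that("greedy subtract never beats the exhaustive-subset BIC oracle", {
  exhaustive_min <- exhaustive_subset_bic
  set.seed(31)
  p <- nita_params(prctile = 50, max_segment = 5, penalty = 2)
  n_cases <- 60
  ok <- 0
  for (k in seq_len(n_cases)) {
    days <- sort(sample(seq(0, 6000, by = 16), 45))
    vd <- sort(sample(days[5:41], 2))
    truth <- approx(c(days[1], vd, days[45]),
                    c(0.8, 0.8, 0.2, 0.2), xout = days)$y
    s <- pixel_series(days, truth + rnorm(45, 0, 0.1))
    built <- nita_build(s, p)
    greedy <- nita_subtract(built, s, p)
    expect_gte(greedy$bic, exhaustive_min(built, s, p) - 1e-9)
    ok <- ok + 1
  }
  expect_equal(ok, n_cases)
  # on a noiseless constructed case greedy attains the exhaustive minimum
  days <- seq(0, 5000, by = 50)
  s0 <- polyline_series(c(0, 2000, 2500, 5000), c(0.8, 0.8, 0.15, 0.15), days)
  built0 <- nita_build(s0, p)
  greedy0 <- nita_subtract(built0, s0, p)
  expect_equal(greedy0$bic, exhaustive_min(built0, s0, p))
})

test_that("fit_pixel composes the stages and is deterministic", {
  days <- seq(0, 4000, by = 80)
  line <- pixel_series(days, rep(0.75, length(days)))
  f <- nita_fit(line, nita_params())
  expect_equal(f$segments, 1L)
  expect_true(f$bailed)
  expect_error(nita_fit(pixel_series(1, 0.5)), "2 valid")
  set.seed(12)
  noisy <- pixel_series(days, 0.7 + rnorm(length(days), 0, 0.15))
  f1 <- nita_fit(noisy, nita_params_study())
  f2 <- nita_fit(noisy, nita_params_study())
  expect_identical(f1, f2)
})

test_that("fitted models round-trip through the dump format", {
  days <- seq(0, 5000, by = 50)
  s <- polyline_series(c(0, 2000, 2500, 5000), c(0.8, 0.8, 0.15, 0.15), days)
  f <- nita_fit(s, nita_params(prctile = 50, max_segment = 5))
  path <- withr::local_tempfile(fileext = ".txt")
  write_nita_model(f, path)
  back <- read_nita_model(path)
  expect_equal(back$breakpoints, f$breakpoints)
  expect_equal(back$segments, f$segments)
  expect_equal(back$bic, f$bic)
  expect_equal(back$noise, f$noise)
})

test_that("median filter degrades gracefully when the kernel exceeds n", {
  expect_warning(v <- nita:::median_filter(c(1, 5, 2), 5), "kernel")
  expect_length(v, 3)
})
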