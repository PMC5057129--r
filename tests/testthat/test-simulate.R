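test_that("the acquisition calendar is fixed, 199 dates, 16-day grained", {
  cal <- landsat_calendar()
  expect_length(cal, 199)
  expect_true(all(diff(cal) %% 16 == 0))
  expect_identical(cal, landsat_calendar())  # deterministic across calls
  # drawing the calendar does not consume the caller's RNG stream
  set.seed(99); a <- runif(1)
  set.seed(99); invisible(landsat_calendar()); b <- runif(1)
  expect_identical(a, b)
})

test_that("trajectory library honours the stratum composition", {
  set.seed(10)
  lib <- make_trajectory_library()
  expect_length(lib, 100)
  segs <- vapply(lib, function(t) t$n_segments, integer(1))
  expect_equal(as.vector(table(segs)), c(39, 11, 35, 11, 4))
  expect_error(make_trajectory_library(n = 10, composition = c(5, 2)),
               "sum")
  # single-segment trajectories have exactly two vertices
  one <- lib[[1]]
  expect_length(one$day, 2)
  # vertices snap to the calendar and disturbance onsets sit in 1990-2006
  cal <- landsat_calendar()
  for (t in lib) {
    expect_true(all(t$day %in% cal))
    if (t$stratum == "inundation") {
      yrs <- day_to_year(t$day[2:3])
      expect_true(all(yrs >= 1989.9 & yrs <= 2007.1))
    }
  }
})

test_that("gap model chains reproduce the stationary valid fraction", {
  g <- gap_model(valid_frac = 0.45, mean_valid_run = 2)
  expect_equal(g$p_vv, 0.5)
  expect_equal(g$p_iv, 0.45 / 0.55 * 0.5, tolerance = 1e-12)
  cal <- landsat_calendar()
  sets <- sample_valid_dates(cal, g, n_sets = 500, seed = 77)
  frac <- mean(vapply(sets, mean, numeric(1)))
  expect_equal(frac, 0.45, tolerance = 0.02)
  # full retention when the chain always stays valid
  g1 <- gap_model(valid_frac = 1, mean_valid_run = 2)
  expect_true(all(sample_valid_dates(cal, g1, 1, seed = 1)[[1]]))
  # determinism under a fixed seed
  expect_identical(sample_valid_dates(cal, g, 3, seed = 5),
                   sample_valid_dates(cal, g, 3, seed = 5))
})

test_that("noise models hit the requested total SD and clip to [-1, 1]", {
  cal <- landsat_calendar()
  truth <- structure(list(day = c(cal[1], cal[199]), value = c(0.5, 0.5),
                          n_segments = 1L, stratum = "stable"),
                     class = "ideal_trajectory")
  # sd = 0 reproduces the polyline exactly
  z <- synthesize_pixel(truth, cal, noise_model("gaussian", sd = 0), seed = 1)
  expect_equal(z$value, rep(0.5, 199))
  # gaussian residual SD ~ 0.2
  set.seed(3)
  g <- replicate(30, synthesize_pixel(truth, cal, noise_model("gaussian"),
                                      seed = sample.int(1e6, 1))$value - 0.5)
  expect_equal(sd(g), 0.2, tolerance = 0.02)
  # contaminated mixture also totals SD 0.2 and skews downward
  set.seed(4)
  cns <- replicate(60, synthesize_pixel(truth, cal, noise_model(),
                                        seed = sample.int(1e6, 1))$value - 0.5)
  expect_equal(sd(cns), 0.2, tolerance = 0.02)
  expect_lt(mean(cns), 0)
  expect_true(all(cns >= -1.5 & cns <= 0.5))  # clipped at -1 overall
  # empirical resampling of a symmetric pool has ~ zero-mean residuals
  pool <- c(-0.1, -0.05, 0, 0.05, 0.1)
  set.seed(5)
  e <- replicate(50, synthesize_pixel(truth, cal,
                                      noise_model("empirical", pool = pool),
                                      seed = sample.int(1e6, 1))$value - 0.5)
  expect_equal(mean(e), 0, tolerance = 0.01)
  expect_true(all(vapply(e, function(x) min(abs(x - pool)) < 1e-12,
                         logical(1))))
  expect_error(noise_model("empirical"), "pool")
})

test_that("evaluate_fits computes zero metrics for perfect fits and signed date errors", {
  cal <- landsat_calendar()
  tr <- inundation_truth(cal)
  perfect <- bp_model(tr$day, tr$value)
  perfect$distances <- rep(0, 4)
  tab <- evaluate_fits(list(perfect), list(tr))
  expect_equal(tab$seg_err, 0)
  expect_equal(tab$rmse, 0)
  expect_equal(tab$start_err, 0)
  expect_equal(tab$nadir_err, 0)
  expect_false(tab$miss)
  # shifted breakpoints: start 10 days early, nadir 30 days late
  shifted <- bp_model(tr$day + c(0L, -10L, 30L, 0L), tr$value)
  tab2 <- evaluate_fits(list(shifted), list(tr))
  expect_equal(tab2$start_err, -10)
  expect_equal(tab2$nadir_err, 30)
  # a single-segment fit of the 3-segment truth is a miss with seg error 2
  flat <- bp_model(tr$day[c(1, 4)], c(0.5, 0.5))
  tab3 <- evaluate_fits(list(flat), list(tr))
  expect_equal(tab3$seg_err, 2)
  expect_true(tab3$miss)
  expect_true(is.na(tab3$nadir_err))
})

test_that("the default assessment design emits 100 x dates x noise pixels", {
  set.seed(2)
  lib <- make_trajectory_library(n = 5, composition = c(2, 1, 1, 1, 0))
  res <- run_assessment(library = lib, n_date_sets = 2, n_noise_sets = 2,
                        seed = 13)
  expect_equal(nrow(res$pixels), 5 * 2 * 2)
  expect_equal(dim(res$manifest$date_seeds), c(5, 2))
  expect_equal(dim(res$manifest$noise_seeds), c(5, 2, 2))
  expect_true("overall" %in% res$summary$stratum)
  # reproducibility: the same seed gives the identical table
  res2 <- run_assessment(library = lib, n_date_sets = 2, n_noise_sets = 2,
                         seed = 13)
  expect_identical(res$pixels, res2$pixels)
})

test_that("a manifest sub-seed regenerates a single pixel exactly", {
  set.seed(2)
  lib <- make_trajectory_library(n = 2, composition = c(1, 0, 1, 0, 0))
  res <- run_assessment(library = lib, n_date_sets = 2, n_noise_sets = 2,
                        seed = 21)
  cal <- landsat_calendar()
  ti <- 2L; di <- 1L; ni <- 2L
  vmask <- sample_valid_dates(cal, gap_model(), 1,
                              seed = res$manifest$date_seeds[ti, di])[[1]]
  sim <- synthesize_pixel(lib[[ti]], cal[vmask], noise_model(),
                          seed = res$manifest$noise_seeds[ti, di, ni])
  refit <- nita_fit(sim, res$manifest$params)
  row <- res$pixels[res$pixels$trajectory == ti & res$pixels$date_set == di &
                      res$pixels$noise_set == ni, ]
  expect_equal(refit$segments, row$fit_segments)
})

test_that("parameter sweep: singleton grid matches a direct run; penalty calms noisy flats", {
  set.seed(6)
  lib <- make_trajectory_library(n = 4, composition = c(4, 0, 0, 0, 0))
  grid1 <- data.frame(penalty = 4)
  sw <- parameter_sweep(grid1, library = lib, n_date_sets = 2,
                        n_noise_sets = 2, seed = 31)
  direct <- run_assessment(library = lib, params = nita_params_study(),
                           n_date_sets = 2, n_noise_sets = 2, seed = 31)
  ov <- direct$summary[direct$summary$stratum == "overall", ]
  expect_equal(sw$seg_mae, ov$seg_mae)
  expect_equal(sw$rmse, ov$rmse)
  # raising penalty never increases mean fitted segments on 1-segment truths
  sw2 <- parameter_sweep(data.frame(penalty = c(1, 8, 64)), library = lib,
                         n_date_sets = 2, n_noise_sets = 2, seed = 31)
  segs <- sw2$seg_mae   # truths have 1 segment: MAE = mean extra segments
  expect_true(all(diff(segs) <= 1e-9))
})
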