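# nita

Noise-insensitive trajectory analysis for cloud-gapped satellite time
series.

Dense Landsat records over the humid tropics lose half or more of their
acquisitions to cloud, and the surviving dates still carry remnant
contamination that depresses NDVI. `nita` fits piecewise-linear
trajectories directly to each pixel's irregular, gappy record and turns
them into disturbance histories. It was built around a riverine
mining-impact setting - forest inundation by tailings deposition upstream,
suspended-sediment enrichment at the estuary downstream - and ships every
piece needed to reproduce that style of analysis at desk scale: the
fitter, the disturbance classifier, a red-band suspended-particulate-
matter (SPM) retrieval with trident-transect sampling, plain-text raster
ingestion, and a simulation harness that measures the fitter's accuracy
under controlled cloud-gap and noise conditions.

## The algorithm

For a pixel with valid observation dates `x` and NDVI values `y`, the
fitted model is an ordered set of breakpoints interpolated linearly.
Fitting runs in five stages:

1. *noise* = median |forward difference| of `y`;
2. an initial single segment between the record endpoints, knot values
   from a windowed percentile (`prctile`; 90 tracks the upper envelope
   through cloud-dark noise);
3. bail out with the single segment unless (mean orthogonal error) /
   noise exceeds `bail_thresh`;
4. *build*: insert breakpoints at the date of maximum median-filtered
   orthogonal error (kernel `2*filt_dist + 1`) until `max_segment`
   segments exist;
5. *subtract*: greedily delete interior breakpoints while the
   Bayesian Information Criterion
   `BIC = penalty * segs * ln(N) - 2 logL` decreases, `logL` being the
   lognormal log-likelihood of the orthogonal distances.

A fitted trajectory is classified by merging consecutive declining
segments: a drop from above 0.70 to below 0.40 NDVI at more than
0.10 NDVI/yr is a *disturbance*; the same crossing at a lower rate is a
*decline*. SPM is retrieved from red water-leaving reflectance as
`A * rho / (1 - rho / C)` with `A = 327.84 g/m^3`, `C = 0.1708`
(reflectance above ~17% is outside the model's domain and masked).

## Worked example

Simulate one cloud-gapped, noisy "single inundation" pixel and fit it:

```r
library(nita)
cal   <- landsat_calendar()               # fixed 199-date archive, 1987-2014
set.seed(42)
lib   <- make_trajectory_library(calendar = cal)
truth <- lib[[60]]                        # 3-segment inundation trajectory
keep  <- sample_valid_dates(cal, gap_model(), 1, seed = 7)[[1]]  # 45% valid
sim   <- synthesize_pixel(truth, cal[keep], noise_model(), seed = 9)
sim
#> pixel_series: 83 observations (83 valid), 1987-02-20 to 2014-07-24
fit <- nita_fit(sim, nita_params_study())  # prctile 90, bail 2, penalty 4
fit
#> nita_model: 4 segment(s), 83 observations, noise 0.02448, BIC -260.38
#>   breakpoints: (1987-02-20, 0.754) (1996-01-28, 0.730) (1997-03-19, 0.278) (2003-08-27, 0.166) (2014-07-24, 0.184)
classify_trajectory(fit)
#>   date_before_disturbance date_of_nadir start_value nadir_value magnitude
#> 1                    9523          9939        0.73       0.278     0.453
#>   drop_rate event_class recovered
#> 1     0.397 disturbance     FALSE
```

The true decline ran 1996-01-12 to 1997-05-22; from 83 surviving
observations with SD-0.2 noise the fitted event starts 16 days late and
bottoms out 64 days early, at a drop rate of 0.40 NDVI/yr - a
disturbance. Ordinal days (9523 = 1996-01-28) convert with
`as.Date(9523, origin = "1970-01-01")`.

The same fitter runs over raster stacks (`load_stack()` on ASCII-grid
reflectance + mask scenes, `fit_image()` for date-of-disturbance,
segment-count and event-class maps), and `run_assessment()` measures it
against a 100-trajectory synthetic library under the study's gap and
noise conditions. A thin CLI exposes the main entry points:

```sh
Rscript inst/cli/nita.R validate --seed 1 --date-sets 10 --noise-sets 10 --out metrics.csv
```

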