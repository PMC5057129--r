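---
title: "Noise-insensitive trajectory analysis: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noise-insensitive trajectory analysis: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nita)
```

## The problem

Dense Landsat time series over humid-tropical landscapes are dominated by
cloud: half or more of the acquisitions at a pixel may be missing or
contaminated, and the survivors still carry remnant haze, shadow and cloud
edges that depress NDVI. Annual-composite change-detection methods discard
most of that record; methods that assume regular sampling cannot use it.
NITA (noise-insensitive trajectory analysis) fits a piecewise-linear
trajectory directly to the irregular per-pixel record, so that acute events
(forest inundation by riverine tailings deposition, in the motivating
application) and protracted processes (urbanization-driven decline,
regrowth) are both captured, with no sub-annual phenology model.

## The model

A pixel's history is a set of valid observation dates $x$ (integer days)
with index values $y$ (NDVI in $[-1, 1]$). The fitted object is an ordered
set of breakpoints $(x_j, y_j)$ - the two record endpoints plus up to
`max_segment - 1` interior vertices - interpolated linearly. Fitting
proceeds in five stages (`nita_fit()`):

1. **Noise.** `estimate_noise()` is the median absolute forward difference
   of consecutive valid values. Absolute differences are used because the
   statistic must measure noise magnitude; signed forward differences have
   median near zero for any stationary series.
2. **Initial fit.** A single segment between the first and last
   observation dates, endpoint values from the windowed quantile rule
   below.
3. **Bail-out.** If the mean orthogonal distance of the initial fit,
   divided by the noise, does not exceed `bail_thresh`, the single-segment
   model is adopted. The mean distance is used as the error summary: a
   single robust scalar commensurate with the noise scalar. A zero-noise
   series bails only when the fit is (numerically) perfect.
4. **Build.** Breakpoints are inserted one at a time at the date of
   maximum *filtered* orthogonal error - the per-observation distances are
   median-filtered with a `2 * filt_dist + 1` kernel so isolated outliers
   cannot attract a breakpoint - until `max_segment` segments exist.
5. **Subtract.** Greedy backward elimination: each interior breakpoint is
   tentatively removed, distances are recomputed, and the removal that
   most lowers the BIC is accepted; elimination stops when no removal
   lowers it. The criterion is
   $\mathrm{BIC} = \textit{penalty} \cdot \textit{segs} \cdot \ln N - 2\log L$,
   with $\log L$ the log-likelihood of the orthogonal distances under a
   lognormal distribution fitted to them by maximum likelihood
   (population-variance estimator). Distances and the fitted
   $\hat\sigma$ are floored at $10^{-6}$ so that a degenerate (perfect)
   fit keeps a finite likelihood.

Orthogonal (perpendicular) distances are computed in a rescaled plane:
dates are expressed in years divided by `xy_scale` (default 1) and values
in index units. Rate thresholds elsewhere in the package use 365.25
days per year.

## The knot rule

Inserted breakpoints take their value from the observations around the
insertion date: the `prctile`-th percentile (linear interpolation between
order statistics - the one percentile definition used package-wide) of a
window of up to `filt_dist` observations on each side. `prctile = 50`
fits the median of the data; `prctile = 90` tracks the upper envelope,
which is the appropriate choice when residual contamination is one-sided
(clouds only ever depress NDVI).

Two refinements matter and are worth stating precisely:

* **Time cap.** The window is additionally capped at
  `filt_dist * revisit_days` days (default 3 x 16 d) on either side, with
  the center and its immediate index neighbours always retained. Without
  the cap, a window can straddle a multi-month cloud gap and mix
  pre-disturbance with post-disturbance values, in which case an
  upper-percentile knot near the bottom of a drop is pulled far above the
  data and the fitted nadir drifts late by several observations.
  Endpoint knots use the uncapped index window: there is no interior
  corner beyond a record end to protect, and robustness there matters
  more.
* **Exactness escape.** If the (uncapped) window is *exactly* piecewise
  linear about its center - which requires at least three exactly
  collinear points on a side, an event of probability zero under noise -
  the observed center value is returned unchanged. A noiseless series
  sampled from a piecewise-linear truth is therefore refitted to machine
  precision, including sloping terminal segments and v-shaped corners, a
  property the test suite checks across the whole trajectory library.

Similarly, the build stage uses the median-filtered error to choose the
*neighbourhood* of insertion, then pins the breakpoint date at the raw
error maximum within `filt_dist` observations of it. The filtered profile
plateaus around a corner; without the second step the breakpoint can land
one observation off the corner permanently, since the median filter then
hides the remaining single-point residual.

## Tunable parameters

| parameter | units | default | study set | role |
|---|---|---|---|---|
| `prctile` | percent | 50 | 90 | data quantile the fit tracks |
| `bail_thresh` | ratio | 1 | 2 | error/noise gate for adding breakpoints |
| `max_segment` | segments | 10 | 10 | build-stage ceiling |
| `filt_dist` | observations | 3 | 3 | error-filter kernel radius and knot window radius |
| `penalty` | multiplier | 1 | 4 | severity of the BIC complexity term |
| `xy_scale` | years per index unit | 1 | 1 | orthogonal-distance axis scaling |
| `revisit_days` | days | 16 | 16 | time cap per window step (Landsat revisit) |

`nita_params_study()` returns the study set used for cloud-heavy tropical
disturbance mapping.

## Disturbance classification

`classify_trajectory()` merges maximal runs of declining fitted segments
into candidate events; segments with slope above `-flat_tol`
(default 0.01 NDVI/yr, a tenth of `rate_cut`) are treated as flat so that
noise-level drift in a post-disturbance plateau cannot extend an event to
the end of the record. An event is a **disturbance** when the fitted value
drops from above 0.70 to below 0.40 at more than 0.10 NDVI/yr (start = last
run breakpoint at or above 0.70; rate measured to the run minimum); the
same crossing at a lower rate is a **decline**. Qualification uses the run
minimum so that relaxing `rate_cut` can only add disturbances. The
*reported* date of nadir is where the rapid decline bottoms out: the last
breakpoint below 0.40 reached by a segment steeper than `rate_cut`,
falling back to the run minimum for slow declines - on a fitted staircase
this dates the bottom of the drop rather than the end of a noise-level
tail. Thresholds are applied to fitted breakpoint values, not raw
observations: the model is the denoised estimate. Recovery means a later
breakpoint above 0.40 following a rising segment.

Landscape summaries - `date_of_disturbance()` (nadir of the earliest
disturbance), `cumulative_area()` (calendar-year bucketing by the nadir
year), `annual_rate_correlation()` (Pearson r of annual disturbance rate
against a production series) - exist so a full-archive analysis can be
reproduced mechanically, though this package ships no satellite archive.

## SPM retrieval and transect aggregation

Coastal suspended particulate matter is retrieved from red-band
water-leaving reflectance as $A\rho_w / (1 - \rho_w / C)$ with
$A = 327.84\ \mathrm{g\,m^{-3}}$ and $C = 0.1708$, coefficients specific
to the 660 nm Landsat TM/ETM+ band. The retrieval is positive, increasing
and convex on $[0, C)$ and diverges at $C$; reflectances at or above $C$
(about 17%) are masked invalid rather than clipped - they indicate silt or
unmasked cloud, outside the model's domain. Sampling uses three-pronged
"trident" transects fanning out from a river outlet (prong offsets of
±30 degrees, a geometry choice; 67 points per prong gives the 201-point
configuration used at 2 km). Spatial aggregation per image date is the
median over transect points (robust to unmasked cloud edges); temporal
aggregation is the 90th percentile, reflecting that most sediment flux in
mountain-fed rivers moves on a few high-flow days. Impacted-versus-
reference comparisons use Welch's unequal-variance two-sample t-test -
the variances have no reason to be equal - on per-date medians, per year
and per period; degenerate (zero-variance) samples yield no test rather
than an error.

## The synthetic study conditions

The accuracy-assessment machinery reconstructs the validation design at
desk scale; none of the original archive is required.

* **Calendar.** A fixed 199-date acquisition calendar over 1987-2014,
  drawn once from a run-structured (Markov) retention of the 16-day
  revisit grid: scenes survive in short consecutive runs (mean 2)
  separated by longer losses, as in a real single-path archive. The
  calendar is deterministic - identical across seeds - and so is a study
  condition, not a random variable.
* **Trajectory library.** 100 piecewise-linear truths in five strata -
  stable forest (1 segment, 39), urbanization decline (2, 11), single
  inundation without recovery (3, 35), inundation with regrowth (4, 11),
  braided-river disturbance/recovery (5, 4) - so that 10 x 10 replication
  yields the 3900/1100/3500/1100/400 pixel split. Disturbance onsets are
  uniform in 1990-2006, pre-disturbance NDVI 0.74-0.85, post-disturbance
  0.08-0.22, drop durations 0.5-2.5 years; vertices snap to calendar
  dates, as manual delineations from real pixel histories would. The
  library emulates such manual delineations rather than shipping any;
  strata and composition are fixed, the shapes within them are drawn at
  simulation time.
* **Gaps.** Per-pixel validity is a two-state Markov chain over the
  calendar with stationary valid probability 0.45 (55% mean cloud cover)
  and mean valid-run length 2 acquisitions, emulating temporally
  autocorrelated cloud.
* **Noise.** The default noise is a contamination mixture: clear-sky
  Gaussian noise (SD 0.015, typical of stable dense-canopy NDVI) plus,
  with probability 0.3, an exponential downward excursion whose mean is
  solved so the **total SD is exactly 0.2 NDVI**. The downward skew is
  what makes an upper-envelope percentile the right fitting quantile; a
  symmetric Gaussian at SD 0.2 would place the 90th-percentile envelope
  ~0.25 above truth and no parameter set could fit well. A pure Gaussian
  kind and an empirical-resampling kind are provided for sensitivity
  work. Simulated values are clipped to $[-1, 1]$.

Every random quantity flows through one seed; the run manifest records
the per-trajectory, per-date-set and per-noise-draw sub-seeds so any
single simulated pixel can be regenerated exactly.

What the generator does **not** emulate: spatially coherent (2-D) cloud
fields, phenology, sensor-to-sensor calibration differences, geolocation
error, and real archives' seasonal acquisition bias. Passing the
simulated assessment therefore demonstrates noise- and gap-resilience
under the stated conditions, not end-to-end accuracy on a real archive.

## Metrics and problem sizes

`evaluate_fits()` reports, per simulated pixel: the absolute error in the
number of segments; the RMSE between fitted and true trajectories on a
daily grid over the fitted span; and, for truths containing a
disturbance, the signed and absolute day offsets of the
date-before-disturbance and date-of-nadir breakpoints, with fits that
find no disturbance counted as misses and excluded from the date means.
Truth and fit are classified by the same rules, so the comparison is
internally consistent. The full assessment is 100 trajectories x 10 date
sets x 10 noise draws = 10,000 fits (a few minutes on one CPU); the
parameter sweep and several tests use reduced replication of the same
design.

Two systematic behaviours of the assessment are worth flagging. First,
the date errors carry opposite directional biases, both gap-driven: the
decline start is dated early (the last clear pre-drop observation
precedes the true onset) and the nadir late. Second, the nadir bias has
an algorithmic floor: with upper-percentile window knots, the first
clear observation after a corner cannot carry a low breakpoint value
while its window still contains a pre-corner observation, so the fitted
nadir is bounded below by roughly the second clear post-corner
observation - about one mean gap plus model error under the default
conditions. Segment-count and start-date accuracy do not share this
floor.

## Numerical choices and degenerate inputs

* Percentiles: linear interpolation between order statistics, everywhere.
* Median filter: interior kernel `2 * filt_dist + 1`; at the series ends
  the window shrinks symmetrically. Kernels longer than the series
  degrade to the largest odd width that fits, with a warning.
* Ties in the build-stage argmax resolve to the earliest date; dates
  already hosting a breakpoint are ineligible.
* Distances and $\hat\sigma$ floors: $10^{-6}$ (see above); the
  zero-noise bail comparison uses a $10^{-12}$ tolerance.
* Two valid observations fit the exact line through both points; fewer
  than two raise an insufficient-data error. `fit_image()` converts
  per-pixel failures to nodata instead of aborting a map.
* NDVI with a zero denominator marks the date invalid; negative
  reflectance is an input error. Negative SPM retrievals are masked, not
  clipped.
* All fitting is deterministic: refitting the same series with the same
  parameters is bit-identical, and maps rerun identically.

## Raster I/O

Grids are read and written as plain-text ESRI ASCII grids with row 1 the
northernmost row, pixel-center map coordinates, and a configurable
integer mask-code policy (default fmask-style: clear and water valid).
Scene dates parse from collection-era and legacy Landsat identifiers,
with a sidecar CSV override for synthetic fixtures. This keeps the whole
toolchain text-only and dependency-light; the trade-off is that
projection metadata beyond the affine grid is not carried.
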