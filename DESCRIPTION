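Package: nita
Title: Noise-Insensitive Trajectory Analysis for Cloud-Gapped Satellite
    Time Series
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Piecewise-linear temporal segmentation of irregular,
    cloud-gapped spectral-index time series (NITA): robust percentile knot
    fitting, breakpoint insertion at maximum filtered orthogonal error,
    and backward elimination under a lognormal-likelihood Bayesian
    Information Criterion. Includes vegetation disturbance classification
    from fitted trajectories (date-of-disturbance, cumulative disturbed
    area, production-rate correlation), single-band retrieval of coastal
    suspended particulate matter from red reflectance with trident-transect
    spatio-temporal aggregation, a simulation harness for accuracy
    assessment under realistic cloud-gap and noise models, and plain-text
    raster stack ingestion with per-pixel dispatch of the fitter.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
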