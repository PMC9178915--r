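Package: segmap
Title: Street-Segment Air Pollution Maps from Mobile Monitoring with
    Mixed-Effects Shrinkage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for turning 1 Hz mobile air-quality drive traces into
    long-term per-street-segment NO2 maps. Raw records are filtered,
    snapped to 50 m street segments, corrected for sampling time using a
    fixed reference station, and aggregated to drive-pass means and a
    per-segment "mean of means" (the data-only map). A supervised
    forward-stepwise land-use regression (LUR) provides a smooth
    fixed-effects surface, and a random-intercept linear mixed model
    fitted by profiled REML blends the two: per-segment best linear
    unbiased predictors shrink noisy segment means toward the LUR surface
    in proportion to their sampling uncertainty. Includes a synthetic
    campaign generator with the sampling structure of real mobile
    campaigns (Poisson drive-pass revisits, skewed pass durations,
    diurnal/weekly drift shared with the reference station) and a
    validation battery (nearest-segment matching within a radius,
    Spearman correlation, RMSE, bias and Bland-Altman summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
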