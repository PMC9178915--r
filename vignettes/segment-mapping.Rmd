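---
title: "Mapping street-segment NO2 from mobile monitoring: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping street-segment NO2 from mobile monitoring: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A car-mounted 1 Hz NO2 monitor driven through a city yields millions of
short, irregular samples: a typical street segment is seen for about eight
seconds at a time, on roughly seven different days, at whatever hour the
car happened to pass. Turning such traces into a *long-term* per-segment
concentration map has to address three things at once:

1. **Sampling-time bias.** Concentrations depend strongly on hour and
   weekday; a segment only measured during morning rush hours looks
   dirtier than it is.
2. **Sampling noise.** Seven short passes give a noisy segment mean; a
   purely empirical ("data-only") map is honest about local variation but
   jumpy.
3. **Smoothing loss.** A land-use regression (LUR) on covariates such as
   traffic intensity and population density is stable but erases exactly
   the street-by-street ("hyperlocal") variation mobile monitoring is
   meant to capture.

`segmap` implements the full chain: range filtering, nearest-segment
assignment, reference-station temporal correction, drive-pass
aggregation, a supervised stepwise LUR, and — the core — a
random-intercept linear mixed model whose BLUPs blend the data-only and
LUR maps segment by segment.

## The model

Let `y_ik` be the mean of the 1 Hz records of drive-pass `k` on segment
`i` (a drive-pass is one calendar day on one segment), and `x_i` the
segment's covariates. The mixed model is

    y_ik = x_i' beta + b_i + e_ik,
    b_i ~ N(0, sigma2_b),   e_ik ~ N(0, sigma2_e),

with one random intercept per segment. Writing `ybar_i` for the mean of
the `n_i` drive-pass means, the BLUP of the segment deviation is

    bhat_i = w_i (ybar_i - x_i' betahat),
    w_i = n_i sigma2_b / (sigma2_e + n_i sigma2_b),

so the mixed prediction `x_i' betahat + bhat_i` is a convex combination
`w_i ybar_i + (1 - w_i) x_i' betahat` of the data-only mean and the LUR
surface: segments with many passes or strong between-segment signal keep
their own data (`w_i -> 1`), sparsely measured segments are shrunk toward
the regression surface, and unmeasured segments fall back to it entirely.
If the random effects vanish (`sigma2_b = 0`) the map *is* the LUR map.

### Fitting

Variance components are estimated by REML (ML by flag); REML's
degrees-of-freedom correction matters because the variance components
directly set the shrinkage weights. Because the random structure is a
single intercept and covariates are segment-constant, everything profiles
analytically in the variance ratio `lambda = sigma2_b / sigma2_e`: with
per-segment GLS weights `w_i = n_i / (1 + lambda n_i)`,

* `betahat(lambda)` solves the weighted normal equations over segment
  means,
* the profiled residual variance is
  `sigma2_e(lambda) = [SSW + sum_i w_i (ybar_i - x_i' betahat)^2] / (N - p)`
  with `SSW` the pooled within-segment sum of squares, and
* the restricted deviance needs only `sum_i log(1 + lambda n_i)` and the
  log-determinant of the p x p weighted cross-product.

The fit is then a safeguarded one-dimensional Brent search over
`log(lambda)` on `[1e-8, 1e8]` (argument tolerance 1e-9) with an explicit
evaluation at the boundary `lambda = 0`, which is admissible and taken
whenever it does not increase the deviance. No N x N matrix is formed;
fitting 35,000 passes on 5,000 segments takes milliseconds. Tests verify
the solution against a dense-matrix grid-plus-golden-section maximiser
and against an independent mixed-model implementation.

Degenerate inputs are handled explicitly: if the segment means are fitted
perfectly at `lambda = 0` (zero residual, as in noise-free simulations)
both components are reported as 0 and the fit is flagged `degenerate`;
data in which every segment has a single pass are refused because
`sigma2_e` is unidentifiable.

### Two-stage fixed effects

The fixed-effect covariates are the LUR-selected set, and the mixed fit
re-estimates their coefficients by GLS (the default). A `freeze_beta`
mode instead keeps the OLS LUR coefficients fixed and estimates only the
variance components; it exists because "taking the fixed effects from the
LUR model" can be read either way, and the choice is worth an explicit
switch. Re-estimation is the default because it is the joint-likelihood
answer and changes coefficients only slightly on realistic designs.

## The pipeline stages and their parameters

* **Range filter**: keep `[0, 500]` ug/m3, inclusive on both bounds —
  removal is of values strictly below 0 or strictly above 500. Counts
  removed at each bound are reported.
* **Segment assignment**: nearest polyline within `max_dist = 50` m
  (configurable); exact distance ties break to the smaller segment id so
  assignment is deterministic. A uniform grid index keeps snapping linear
  in the number of records; trajectory-aware map matching is out of
  scope.
* **Temporal correction**: per time window `w`,
  `corrected = measured + (overall_mean - ref_mean_w)`, with window means
  and the overall mean taken from a fixed reference station that runs day
  and night over the whole campaign. The overall mean is the plain mean
  of the full series (not a mean of window means), so corrected values
  are anchored to the true long-term level including nights and weekends
  that the car never samples. Default windows are hour-of-day x weekday;
  with daytime weekday driving this is 14 hourly bins per weekday. A
  multiplicative (`ratio`) variant is provided behind a flag; additive is
  the default reading of "difference between the overall average and the
  window average". Correction is applied at the 1 Hz record level, before
  aggregation. Records in windows with no reference data are an error,
  never silently passed through.
* **Aggregation**: drive-pass = (segment, calendar day); segment summary
  = unweighted mean of pass means ("mean of means", so a two-second pass
  counts as much as a minute-long one), SEM = sample SD of pass means /
  sqrt(n_passes), undefined for single-pass segments.
* **LUR**: supervised forward stepwise OLS. Entry requires the candidate
  to (i) carry its expected sign, (ii) not flip any entered coefficient's
  sign, and (iii) raise adjusted R2 by at least `gain_min = 0.01`; after
  selection, covariates with `p >= 0.10` or a violated sign are dropped
  and the model refitted until stable. These are the standard supervised
  conventions of the LUR literature; all three thresholds are arguments.
  OLS is unweighted over segments. Perfect fits (possible in noise-free
  simulations) map their undefined p-values to 0.
* **Validation**: external points match their nearest segment within 20 m
  (default); metrics are Spearman correlation (average ranks on ties),
  RMSE, `mean_bias = mean(test - ref)` — positive when the map exceeds
  the external reference, a convention recorded inside every report —
  relative bias as a percentage of the mean reference value, and
  Bland-Altman mean difference, 1.96-SD limits of agreement and
  difference-vs-average slope. Summary blocks use inclusive
  linear-interpolation (type 7) quantiles.

An optional `facade_adjust` scalar (e.g. 0.8) down-scales all map layers
to translate on-road measurements to building-facade levels; it is off by
default because it is a post-hoc calibration, not part of the model.

## What the synthetic campaign emulates

Real mobile campaigns deposit no raw traces, so the package ships a
generator whose defaults are the study conditions under which everything
is tested:

* a connected grid network of exactly 50 m segments with four covariates
  (own-street traffic, a correlated buffer-style traffic proxy, a smooth
  population field, port proximity), each declared with a positive
  expected sign; the buffer proxy does not enter the generating surface,
  so selection has a realistic decoy;
* truth `C_i = x_i' beta_true + u_i`, `u_i ~ N(0, 16)` (sigma_b = 4
  ug/m3 of hyperlocal deviation), redrawn on the rare draws that would
  make `C_i` non-positive;
* pass counts `1 + Poisson(6)` on distinct weekdays (mean 7), pass
  durations with median 8 s and interquartile range 3-10 s. No lognormal
  has that median with those quartiles (a lognormal's median is the
  geometric mean of its quartiles, about 5.5 here), so durations are
  drawn from a monotone piecewise-linear quantile function through
  (25% -> 3 s, 50% -> 8 s, 75% -> 10 s) with tails at 1 and 25 s,
  rounded to whole seconds;
* between-pass variance `sigma2_e = 25` split into a per-pass shock
  `N(0, sigma2_e (1 - 1/s))` plus per-second instrument noise
  `N(0, sigma2_e)`, so a pass mean has variance exactly `sigma2_e`
  whatever its duration `s`. The split matters: putting all the variance
  in per-second noise scaled by `s` would give long passes per-second SDs
  above 10 ug/m3, and the `[0, 500]` filter would then truncate the lower
  tail and bias segment means upward by over 1 ug/m3;
* a shared temporal drift `d(t)`: an hour-of-day profile (daytime high,
  night low) scaled so its mean over the measured window (08:00-22:00,
  weekdays) is exactly the configured amplitude (default 3 ug/m3 — the
  uncorrected sampling bias), a weekday profile that is mean-zero over
  weekdays, and centred AR(1) day effects (SD 3 ug/m3, lag-1
  correlation 0.6). The reference station observes `22 + d(t)` hourly
  plus `N(0, 1.5^2)` noise over a 70-day campaign (10 whole weeks, so the
  drift averages to zero exactly over the reference grid). The AR(1) day
  component is a stand-in — campaign data do not pin down the day-to-day
  autocorrelation of the residual temporal signal — and its parameters
  are exposed in the configuration;
* 0.1% of records replaced by gross outliers uniform on [-20, 600] to
  exercise the filter; GPS noise with SD 3 m.

Coordinates are abstract planar metres with no CRS: all distance
thresholds (50 m snapping, 20 m matching) are metric, and real-data users
must supply projected coordinates. Coordinates that look like geographic
degrees are rejected.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real campaigns: realistic road topology and
route-constrained driving, spatially correlated random effects (truth
deviations are independent across segments), NO/O3 chemistry, meteorology
beyond the shared drift, per-car calibration offsets, and the
on-road-to-facade gradient (exposed only as the scalar above).

## Numerical and testing choices

Problem sizes in the test-suite were chosen to make Monte-Carlo checks
sharp while keeping the default run around a minute: 5,000-segment
campaigns for the headline map comparisons (50 replicates), 2,000
segments x 20 replicates for variance-component recovery, 800 segments x
20 replicates for the temporal-correction check, 30-segment instances for
dense-oracle REML equivalence, and >= 200 randomised cases per
deterministic primitive (filtering, snapping and tie-breaks, mean of
means, SEM, matching, metrics) against brute-force oracles.

Two checks deserve a note on interpretation:

* *Noise-free identity.* With all noise, drift and outliers off and the
  LUR given the generating basis, data-only, LUR and mixed maps all
  reproduce the truth to 1e-8. The stepwise must be allowed to enter
  arbitrarily small exact gains there (`gain_min = 1e-8`), since the
  default 0.01 entry gain deliberately refuses terms that explain less
  than 1% of variance — including the small port term of the generating
  surface.
* *Temporal-correction efficacy.* The correction targets the systematic
  sampling-time bias, and the tests require the city-wide mean bias to
  fall by at least half (observed: ~90%+). Per-segment mean absolute
  error also improves in every replicate, but cannot halve, because most
  of it is sampling noise (`sigma_e / sqrt(7) ~ 1.9` ug/m3) that no
  temporal model can remove.

Known limitations: random effects are spatially independent (no kriging
or CAR smoothing of the BLUP field); there is no uncertainty layer beyond
the SEM map; in-sample R2 is the only LUR diagnostic (no cross-validated
hold-out); the stepwise inherits the usual instabilities of forward
selection under collinearity, mitigated but not removed by the sign
constraints.

## A worked run

```r
library(segmap)
camp <- simulate_campaign(campaign_config(n_segments = 1000), seed = 42)
res  <- run_pipeline(camp)
res$lur        # selected covariates, R2
res$mixed      # variance components, shrinkage
head(res$map)  # per-segment data-only / LUR / mixed layers

truth <- camp$truth$conc_true
cor(truth, res$map$mean_of_means, method = "spearman")
cor(truth, res$map$lur_pred,      method = "spearman")
cor(truth, res$map$mixed_pred,    method = "spearman")
```

On campaigns like this the mixed map consistently ranks the truth at
least as well as both ingredient maps, and its variance falls between the
smooth LUR surface and the noisy data-only map — the behaviour that
motivates the blend.
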