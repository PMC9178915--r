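# segmap

Long-term, street-segment air pollution maps from mobile monitoring, with
mixed-effects shrinkage.

## The problem

Car-mounted 1 Hz NO2 monitors cover every street of a city, but each 50 m
street segment is only sampled for a few seconds at a time (median ~8 s
per pass) on a handful of days (~7 drive-passes), at arbitrary hours.
Three map products compete:

* the **data-only map** — per-segment "mean of means" over drive-passes —
  keeps the street-by-street (hyperlocal) variation but is noisy where
  passes are few;
* a **land-use regression (LUR)** on segment covariates (traffic
  intensity, population density, ...) is smooth and stable but erases the
  hyperlocal signal;
* the **mixed map** blends the two with a random-intercept linear mixed
  model, keeping measured local deviations where the data support them
  and borrowing the regression surface where they do not.

For drive-pass mean *k* on segment *i*:

```
y_ik = x_i' β + b_i + ε_ik ,   b_i ~ N(0, σ²_b) ,   ε_ik ~ N(0, σ²_e)
```

Fitted by profiled REML (an exact 1-D search over λ = σ²_b/σ²_e; no large
matrices), the per-segment BLUP shrinks the observed deviation by
`w_i = n_i σ²_b / (σ²_e + n_i σ²_b)`, so the mixed prediction is the
convex combination `w_i·ȳ_i + (1 − w_i)·x_i'β̂`: more passes, more trust
in the data; unmeasured segments fall back to the LUR surface.

Around the model sit the supporting stages of a mobile campaign: range
filtering to [0, 500] µg/m³, nearest-segment snapping (deterministic
tie-breaks, capped distance), additive temporal correction against a
fixed reference station (hour × weekday windows), drive-pass aggregation,
supervised sign-constrained forward-stepwise LUR, and a validation
battery (nearest-point matching within 20 m, Spearman, RMSE, bias,
Bland–Altman). A synthetic campaign generator with the full sampling
structure (Poisson revisits, skewed pass durations, shared diurnal/weekly
drift, gross outliers) makes every stage testable without any external
data; user data in the same CSV/GeoJSON schemas drop straight in.

## Worked example

```r
library(segmap)
camp <- simulate_campaign(campaign_config(n_segments = 1000), seed = 42)
res  <- run_pipeline(camp)
res$lur
#> <lur_fit> 2 covariate(s) selected of 4 candidates; R2 = 0.522, adj R2 = 0.521, n = 1000
#>        (Intercept)  traffic_intensity population_density
#>         18.2514164          0.7853901          0.6414334
res$mixed
#> <mixed_fit> 1000 segments, 7095 drive-passes; REML
#>   sigma2_b = 16.23, sigma2_e = 44.29
#>        (Intercept)  traffic_intensity population_density
#>         18.3666168          0.7876494          0.6223538
head(res$map[, c("segment_id", "lur_pred", "blup", "mixed_pred",
                 "n_passes", "shrink_w")], 4)
#>   segment_id lur_pred   blup mixed_pred n_passes shrink_w
#> 1          1    22.49 0.4007      22.90        8   0.7456
#> 2          2    22.27 2.4997      24.77        7   0.7194
#> 3          3    22.77 0.5928      23.37       10   0.7855
#> 4          4    23.25 2.3378      25.59        8   0.7456
```

Reading this: the stepwise LUR kept two of four candidate covariates
(R² ≈ 0.52); REML attributes 16.2 µg²/m⁶ of variance to real
between-segment deviations versus 44.3 µg²/m⁶ of pass-to-pass noise, so a
typical 8-pass segment keeps ~75% of its observed deviation
(`shrink_w ≈ 0.75`) and is shrunk a quarter of the way toward the LUR
surface. Against the generator's known truth the blend pays off:

```r
truth <- camp$truth$conc_true
cor(truth, res$map$mean_of_means, method = "spearman")  # 0.906  data-only
cor(truth, res$map$lur_pred,      method = "spearman")  # 0.535  LUR
cor(truth, res$map$mixed_pred,    method = "spearman")  # 0.917  mixed
```

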