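#' Campaign configuration for the synthetic mobile-monitoring generator
#'
#' Bundles every knob of the synthetic campaign. Defaults reproduce the
#' sampling structure of a large city-wide mobile campaign: on average seven
#' drive-passes per segment on distinct days, right-skewed pass durations
#' with median 8 s and interquartile range 3--10 s, measurement between
#' 08:00 and 22:00 on weekdays only, a shared diurnal/weekly drift observed
#' (with noise) at a fixed reference station, and a small fraction of gross
#' outliers to exercise range filtering.
#'
#' @param n_segments number of street segments in the synthetic city.
#' @param mean_passes mean number of drive-passes per segment; pass counts
#'   are `1 + Poisson(mean_passes - 1)` so every segment is measured at
#'   least once.
#' @param sigma2_b true between-segment variance of the deviations from the
#'   covariate surface (ug2/m6).
#' @param sigma2_e true between-pass (within-segment) variance of drive-pass
#'   means (ug2/m6). Pass-level and per-second noise are split so that a
#'   pass mean has exactly this variance whatever the pass duration.
#' @param beta_true named vector of generating coefficients; must contain
#'   `"(Intercept)"`, remaining names must be network covariates. Covariates
#'   absent from `beta_true` do not enter the truth (decoys).
#' @param drift_amplitude amplitude of the deterministic hour-of-day x
#'   weekday drift, ug/m3. The hour profile is scaled so that its mean over
#'   the measured window (08:00--22:00, weekdays) equals exactly
#'   `drift_amplitude`, i.e. uncorrected daytime sampling is biased high by
#'   about this amount.
#' @param day_sd,day_ar marginal SD (ug/m3) and lag-1 autocorrelation of the
#'   AR(1) day-to-day drift component (centred over the campaign).
#' @param campaign_start campaign start date (a Monday keeps whole weeks).
#' @param n_days campaign length in days; a multiple of 7 makes the drift
#'   average to zero exactly over the reference grid.
#' @param ref_level,ref_noise_sd mean level and observation noise SD of the
#'   reference station (ug/m3).
#' @param gps_noise_sd GPS position noise SD in metres.
#' @param outlier_frac fraction of 1 Hz records replaced by gross outliers
#'   drawn uniformly on `outlier_range`.
#' @param outlier_range range of injected outliers (ug/m3).
#' @param n_cars number of monitoring cars.
#' @return A list of class `campaign_config`.
#' @export
campaign_config <- function(n_segments = 5000,
                            mean_passes = 7,
                            sigma2_b = 16,
                            sigma2_e = 25,
                            beta_true = c("(Intercept)" = 18,
                                          traffic_intensity = 0.8,
                                          population_density = 0.6,
                                          port_area = 5),
                            drift_amplitude = 3,
                            day_sd = 3,
                            day_ar = 0.6,
                            campaign_start = as.Date("2019-04-01"),
                            n_days = 70,
                            ref_level = 22,
                            ref_noise_sd = 1.5,
                            gps_noise_sd = 3,
                            outlier_frac = 0.001,
                            outlier_range = c(-20, 600),
                            n_cars = 2) {
  stopifnot(n_segments >= 1, mean_passes >= 1,
            sigma2_b >= 0, sigma2_e >= 0,
            day_sd >= 0, ref_noise_sd >= 0, gps_noise_sd >= 0,
            outlier_frac >= 0, outlier_frac < 1, n_days >= 7)
  if (!"(Intercept)" %in% names(beta_true))
    stop("`beta_true` must contain an \"(Intercept)\" element")
  structure(as.list(environment()), class = "campaign_config")
}

#' Generate the true long-term concentration surface
#'
#' The long-term concentration of segment i is
#' `C_i = x_i' beta_true + u_i`, `u_i ~ N(0, sigma2_b)`: a linear land-use
#' surface plus an independent segment-level deviation (the hyperlocal
#' signal a smooth regression cannot capture). Draws of `u_i` that would
#' make `C_i <= 0` are redrawn, so every generated concentration is
#' positive.
#'
#' @param network a [generate_network()] result.
#' @param config a [campaign_config()].
#' @return Object of class `truth_surface`: data.frame with `segment_id`,
#'   `mu_fixed` (`x_i' beta_true`), `u`, `conc_true`; attributes
#'   `beta_true`, `sigma2_b`.
#' @export
generate_truth <- function(network, config = campaign_config()) {
  beta <- config$beta_true
  covs <- setdiff(names(beta), "(Intercept)")
  X <- covariate_matrix(network$covariates, covs)
  mu <- drop(beta[["(Intercept)"]] + X %*% beta[covs])
  n <- length(mu)
  u <- if (config$sigma2_b > 0) rnorm(n, 0, sqrt(config$sigma2_b)) else numeric(n)
  bad <- which(mu + u <= 0)
  tries <- 0L
  while (length(bad) && tries < 1000L) {
    u[bad] <- rnorm(length(bad), 0, sqrt(config$sigma2_b))
    bad <- bad[mu[bad] + u[bad] <= 0]
    tries <- tries + 1L
  }
  if (length(bad))
    stop("could not draw positive concentrations for ", length(bad),
         " segment(s); check beta_true against the covariate scales")
  structure(
    data.frame(segment_id = network$covariates$segment_id,
               mu_fixed = mu, u = u, conc_true = mu + u),
    beta_true = beta, sigma2_b = config$sigma2_b,
    class = c("truth_surface", "data.frame")
  )
}

# Hour-of-day drift profile, unit amplitude. Mean 0 over the 24 hour bins
# and mean exactly 1 over the measured bins (08:00-21:59), so the
# daytime-weekday sampling bias equals the configured amplitude.
hour_profile <- function(hour) {
  ifelse(hour >= 8 & hour <= 21,
         1 + 0.5 * sin(2 * pi * (hour - 8) / 14),
         -1.4)
}

# Weekday modifier, unit amplitude: mean 0 over Mon-Fri and 0 at weekends,
# so it biases neither weekday sampling nor the full-week reference mean.
weekday_profile <- function(wd) {
  c(0.15, 0.05, 0, -0.05, -0.15, 0, 0)[wd]
}

#' Create the shared temporal drift of a synthetic campaign
#'
#' The city-wide temporal signal added to every measurement and observed at
#' the reference station:
#' `d(t) = A * (h(hour(t)) + w(weekday(t))) + e(day(t))`,
#' a deterministic hour-of-day profile (daytime high, night low), a small
#' weekday profile, and centred AR(1) day-to-day deviations. By
#' construction `d(t)` averages to zero over a whole-week campaign at a
#' regular cadence.
#'
#' @inheritParams generate_truth
#' @return Object of class `campaign_drift`.
#' @export
make_drift <- function(config = campaign_config()) {
  n_days <- config$n_days
  e <- numeric(n_days)
  if (config$day_sd > 0) {
    e[1] <- rnorm(1, 0, config$day_sd)
    for (d in seq_len(n_days - 1L))
      e[d + 1L] <- config$day_ar * e[d] +
        rnorm(1, 0, config$day_sd * sqrt(1 - config$day_ar^2))
    e <- e - mean(e)
  }
  structure(
    list(amplitude = config$drift_amplitude, day_effects = e,
         start = config$campaign_start, n_days = n_days),
    class = "campaign_drift"
  )
}

#' Evaluate the campaign drift at given times
#'
#' @param drift a [make_drift()] result.
#' @param t POSIXct times (UTC), inside the campaign window.
#' @return numeric drift values, ug/m3.
#' @export
drift_at <- function(drift, t) {
  lt <- as.POSIXlt(t, tz = "UTC")
  hour <- lt$hour
  wd <- ((lt$wday + 6L) %% 7L) + 1L  # Mon = 1 ... Sun = 7
  day_idx <- as.integer(floor(as.numeric(
    difftime(t, as.POSIXct(drift$start, tz = "UTC"), units = "days")))) + 1L
  if (any(day_idx < 1L | day_idx > drift$n_days))
    stop("time(s) outside the campaign window covered by the drift")
  drift$amplitude * (hour_profile(hour) + weekday_profile(wd)) +
    drift$day_effects[day_idx]
}

#' Generate the reference-station time series
#'
#' An hourly series covering the full campaign period -- all hours of all
#' days, including nights and weekends -- as a fixed urban monitor would.
#' Values are `ref_level + d(t) + noise`; the station sees the same
#' temporal drift as the mobile measurements, plus independent observation
#' noise, which is what makes temporal correction learnable but imperfect.
#'
#' @inheritParams drift_at
#' @inheritParams generate_truth
#' @return data.frame with `timestamp` (POSIXct UTC, hourly) and
#'   `no2_ugm3`.
#' @export
make_reference <- function(drift, config = campaign_config()) {
  t0 <- as.POSIXct(config$campaign_start, tz = "UTC")
  ts <- t0 + 3600 * (0:(config$n_days * 24L - 1L))
  val <- config$ref_level + drift_at(drift, ts)
  if (config$ref_noise_sd > 0)
    val <- val + rnorm(length(ts), 0, config$ref_noise_sd)
  data.frame(timestamp = ts, no2_ugm3 = val)
}

# Drive-pass duration sampler: right-skewed integer seconds with median 8
# and quartiles (3, 10), via a monotone piecewise-linear quantile function.
rpass_seconds <- function(n) {
  qs <- c(0, 0.25, 0.5, 0.75, 1)
  vs <- c(1, 3, 8, 10, 25)
  pmax(1L, as.integer(round(approx(qs, vs, xout = runif(n))$y)))
}

#' Simulate 1 Hz drive-pass measurement records
#'
#' For each segment draws `K_i ~ 1 + Poisson(mean_passes - 1)` drive-passes
#' on distinct weekdays of the campaign, each starting at a random time in
#' the measured window (08:00--22:00) and lasting `s` seconds drawn from the
#' skewed duration distribution. Each 1 Hz record on segment i at time t is
#'
#' `y = C_i + d(t) + eta_pass + nu`,
#' `eta_pass ~ N(0, sigma2_e * (1 - 1/s))`, `nu ~ N(0, sigma2_e)`,
#'
#' a pass-level shock (short-lived local conditions: plumes, queues, wind)
#' plus per-second instrument noise, split so that a pass mean over its `s`
#' seconds has variance exactly `sigma2_e` regardless of duration.
#' Record coordinates move along the segment with GPS noise, and a small
#' configurable fraction of records is replaced by gross outliers to
#' exercise the range filter.
#'
#' @param network,truth,drift,config campaign pieces (see
#'   [generate_network()], [generate_truth()], [make_drift()],
#'   [campaign_config()]).
#' @param reference reference series from [make_reference()]; passes must
#'   fall inside its time coverage, otherwise generation stops and names
#'   the gap.
#' @return data.frame of `MeasurementRecord`s: `timestamp`, `x`, `y`,
#'   `no2_ugm3`, `car_id`, plus the true `segment_id` of each record (kept
#'   so downstream stages can be run with or without geometric snapping).
#' @export
simulate_passes <- function(network, truth, reference, drift,
                            config = campaign_config()) {
  n_seg <- nrow(network$segments)
  K <- 1L + rpois(n_seg, max(config$mean_passes - 1, 0))

  days_all <- config$campaign_start + 0:(config$n_days - 1L)
  wd <- ((as.POSIXlt(days_all)$wday + 6L) %% 7L) + 1L
  weekdays_pool <- days_all[wd <= 5L]
  K <- pmin(K, length(weekdays_pool))

  # one pass per segment per day: sample distinct days per segment
  pass_day <- unlist(lapply(K, function(k)
    sample(as.integer(weekdays_pool), k)), use.names = FALSE)
  pass_seg <- rep(seq_len(n_seg), K)
  n_pass <- length(pass_seg)
  pass_s <- rpass_seconds(n_pass)
  # start inside 08:00-22:00 with room for the pass itself
  pass_t0 <- as.POSIXct(as.Date(pass_day, origin = "1970-01-01"), tz = "UTC") +
    3600 * sample(8:21, n_pass, replace = TRUE) +
    floor(runif(n_pass, 0, 3600 - pmin(pass_s, 60)))

  idx <- rep(seq_len(n_pass), pass_s)
  off <- sequence(pass_s) - 1L
  t <- pass_t0[idx] + off
  tr <- range(reference$timestamp)
  bad <- t < tr[1] | t > tr[2] + 3599
  if (any(bad))
    stop("reference series does not cover pass times in [",
         format(min(t[bad])), ", ", format(max(t[bad])), "]")

  seg <- pass_seg[idx]
  conc <- truth$conc_true[seg] + drift_at(drift, t)
  if (config$sigma2_e > 0) {
    eta <- rnorm(n_pass, 0, sqrt(config$sigma2_e * (1 - 1 / pass_s)))
    conc <- conc + eta[idx] + rnorm(length(t), 0, sqrt(config$sigma2_e))
  }

  frac <- (off + runif(length(t))) / pass_s[idx]
  sgm <- network$segments
  x <- sgm$x0[seg] + frac * (sgm$x1[seg] - sgm$x0[seg])
  y <- sgm$y0[seg] + frac * (sgm$y1[seg] - sgm$y0[seg])
  if (config$gps_noise_sd > 0) {
    x <- x + rnorm(length(t), 0, config$gps_noise_sd)
    y <- y + rnorm(length(t), 0, config$gps_noise_sd)
  }

  if (config$outlier_frac > 0) {
    out <- runif(length(t)) < config$outlier_frac
    conc[out] <- runif(sum(out), config$outlier_range[1],
                       config$outlier_range[2])
  }

  data.frame(
    timestamp = t, x = x, y = y, no2_ugm3 = conc,
    car_id = paste0("car", ((pass_seg + pass_day) %% config$n_cars + 1L))[idx],
    segment_id = sgm$segment_id[seg]
  )
}

#' Simulate a complete synthetic mobile-monitoring campaign
#'
#' Convenience wrapper: network, truth surface, temporal drift, reference
#' series and 1 Hz drive-pass records, generated in order from one seed.
#'
#' @param config a [campaign_config()].
#' @param seed integer seed; if not `NULL`, [set.seed()] is called so the
#'   whole campaign is reproducible.
#' @return list of class `segmap_campaign` with elements `network`,
#'   `truth`, `drift`, `reference`, `measurements`, `config`, `seed`.
#' @examples
#' camp <- simulate_campaign(campaign_config(n_segments = 30), seed = 42)
#' head(camp$measurements)
#' @export
simulate_campaign <- function(config = campaign_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  network <- generate_network(config$n_segments)
  truth <- generate_truth(network, config)
  drift <- make_drift(config)
  reference <- make_reference(drift, config)
  measurements <- simulate_passes(network, truth, reference, drift, config)
  structure(
    list(network = network, truth = truth, drift = drift,
         reference = reference, measurements = measurements,
         config = config, seed = seed),
    class = "segmap_campaign"
  )
}

#' @export
print.segmap_campaign <- function(x, ...) {
  cat("<segmap_campaign> ", nrow(x$network$segments), " segments, ",
      nrow(x$measurements), " 1 Hz records, ",
      x$config$n_days, "-day campaign",
      if (!is.null(x$seed)) paste0(" (seed ", x$seed, ")"), "\n", sep = "")
  invisible(x)
}
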