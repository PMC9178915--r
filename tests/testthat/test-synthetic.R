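test_that("network construction gives the requested count, 50 m lengths and unique ids", {
  set.seed(11)
  net <- generate_network(4)
  expect_equal(nrow(net$segments), 4)
  expect_equal(nrow(net$covariates), 4)
  expect_equal(net$segments$length, rep(50, 4))
  expect_false(anyDuplicated(net$segments$segment_id) > 0)
  expect_false(anyNA(net$covariates))
  expect_true(all(net$expected_sign %in% c(-1, 1)))
})

test_that("network scales to a full city-sized segment count", {
  set.seed(11)
  net <- generate_network(46664)
  expect_equal(nrow(net$segments), 46664)
  expect_equal(nrow(net$covariates), 46664)
  expect_true(all(net$segments$length > 0 & net$segments$length <= 60))
})

test_that("the same seed reproduces the campaign byte for byte", {
  cfg <- campaign_config(n_segments = 25)
  a <- simulate_campaign(cfg, seed = 99)
  b <- simulate_campaign(cfg, seed = 99)
  expect_identical(a$network, b$network)
  expect_identical(a$truth, b$truth)
  expect_identical(a$reference, b$reference)
  expect_identical(a$measurements, b$measurements)
})

test_that("truth surface degenerates correctly at zero variance and flat coefficients", {
  set.seed(5)
  net <- generate_network(30)
  cfg0 <- campaign_config(n_segments = 30, sigma2_b = 0)
  tr <- generate_truth(net, cfg0)
  expect_equal(tr$conc_true, tr$mu_fixed)
  expect_equal(tr$u, rep(0, 30))

  flat <- campaign_config(n_segments = 30, sigma2_b = 0,
                          beta_true = c("(Intercept)" = 25))
  tr2 <- generate_truth(net, flat)
  expect_equal(tr2$conc_true, rep(25, 30))
})

test_that("segment deviations recover the configured variance at large n", {
  set.seed(21)
  net <- generate_network(10000)
  tr <- generate_truth(net, campaign_config(n_segments = 10000, sigma2_b = 16))
  # sample variance of u: chi-square spread around 16 is well inside this band
  expect_gt(var(tr$u), 14.5)
  expect_lt(var(tr$u), 17.5)
  expect_lt(abs(mean(tr$u)), 3 * 4 / sqrt(10000))
})

test_that("pass durations have median 8 s with IQR close to (3, 10)", {
  set.seed(31)
  meds <- q1s <- q3s <- numeric(20)
  for (r in 1:20) {
    s <- segmap:::rpass_seconds(5000)
    q <- quantile(s, c(0.25, 0.5, 0.75))
    q1s[r] <- q[1]; meds[r] <- q[2]; q3s[r] <- q[3]
  }
  expect_true(all(meds >= 7 & meds <= 9))
  expect_true(all(abs(q1s - 3) <= 1))
  expect_true(all(abs(q3s - 10) <= 1))

  # and the same holds for the durations actually attached to drive-passes
  camp <- simulate_campaign(campaign_config(n_segments = 2000), seed = 31)
  pm <- aggregate_passes(camp$measurements)
  q <- quantile(pm$n_seconds, c(0.25, 0.5, 0.75))
  expect_true(q[2] >= 7 && q[2] <= 9)
  expect_true(abs(q[1] - 3) <= 1 && abs(q[3] - 10) <= 1)
})

test_that("pass counts are 1 + Poisson(mean - 1) with the configured mean", {
  camp <- simulate_campaign(campaign_config(n_segments = 5000), seed = 41)
  pm <- aggregate_passes(camp$measurements)
  counts <- table(pm$segment_id)
  expect_equal(length(counts), 5000)
  expect_true(all(counts >= 1))
  # mean 7, SE of the mean of 5000 draws of 1+Pois(6) is sqrt(6/5000)
  expect_lt(abs(mean(counts) - 7), 3 * sqrt(6 / 5000))

  one <- simulate_campaign(campaign_config(n_segments = 50, mean_passes = 1),
                           seed = 42)
  expect_true(all(table(aggregate_passes(one$measurements)$segment_id) == 1))
})

test_that("noise-free, drift-free records equal the true concentration exactly", {
  cfg <- campaign_config(n_segments = 40, sigma2_e = 0, drift_amplitude = 0,
                         day_sd = 0, ref_noise_sd = 0, outlier_frac = 0,
                         gps_noise_sd = 0)
  camp <- simulate_campaign(cfg, seed = 7)
  truth_of <- camp$truth$conc_true[match(camp$measurements$segment_id,
                                         camp$truth$segment_id)]
  expect_equal(camp$measurements$no2_ugm3, truth_of)
})

test_that("campaign drift averages to zero over the reference grid and to the amplitude over the measured window", {
  set.seed(8)
  cfg <- campaign_config(n_segments = 10, drift_amplitude = 3)
  drift <- make_drift(cfg)
  t0 <- as.POSIXct(cfg$campaign_start, tz = "UTC")
  ts <- t0 + 3600 * (0:(cfg$n_days * 24 - 1))
  d <- drift_at(drift, ts)
  expect_lt(abs(mean(d)), 1e-10)
  lt <- as.POSIXlt(ts, tz = "UTC")
  daytime <- lt$hour >= 8 & lt$hour <= 21 & !(lt$wday %in% c(0, 6))
  # AR(1) day effects add mean-zero noise around the calibrated amplitude
  expect_lt(abs(mean(d[daytime]) - 3), 1.5)
})

test_that("passes outside the reference coverage are refused with the gap named", {
  cfg <- campaign_config(n_segments = 5)
  set.seed(1)
  net <- generate_network(5)
  tr <- generate_truth(net, cfg)
  drift <- make_drift(cfg)
  ref <- make_reference(drift, cfg)
  short_ref <- ref[1:24, ]  # first day only
  expect_error(simulate_passes(net, tr, short_ref, drift, cfg),
               "reference series does not cover")
})
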