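toy_fit <- function() {
  pm <- data.frame(segment_id = c("A", "A", "B", "B"),
                   mean_conc = c(1, 3, 5, 7))
  fit_mixed(pm, data.frame(segment_id = c("A", "B")))
}

test_that("balanced two-segment toy reproduces the one-way ANOVA closed form", {
  fit <- toy_fit()
  # MSW = 2, MSB = 16, sigma2_b = (MSB - MSW)/n = 7, grand mean 4
  expect_equal(unname(fit$beta), 4, tolerance = 1e-8)
  expect_equal(fit$sigma2_e, 2, tolerance = 1e-6)
  expect_equal(fit$sigma2_b, 7, tolerance = 1e-5)
})

test_that("BLUPs shrink observed deviations by n*s2b/(s2e + n*s2b)", {
  fit <- toy_fit()
  expect_equal(fit$segments$shrink_w, rep(0.875, 2), tolerance = 1e-6)
  expect_equal(blup(fit, "A"), 0.875 * (2 - 4), tolerance = 1e-5)
  expect_equal(blup(fit, "B"), 0.875 * (6 - 4), tolerance = 1e-5)
  expect_error(blup(fit, "Z"), "unknown segment")
})

test_that("profiled fit matches the dense grid-plus-refine likelihood maximiser", {
  for (seed in 1:3) {
    set.seed(seed)
    m <- 25
    n_i <- sample(2:8, m, replace = TRUE)
    X <- cbind(1, z1 = rnorm(m), z2 = runif(m))
    beta <- c(10, 2, -1)
    b <- rnorm(m, 0, 2)
    y <- rep(drop(X %*% beta) + b, n_i) + rnorm(sum(n_i), 0, 1.5)
    seg <- rep(seq_len(m), n_i)
    pm <- data.frame(segment_id = seg, mean_conc = y)
    covs <- data.frame(segment_id = seq_len(m), z1 = X[, 2], z2 = X[, 3])
    fit <- fit_mixed(pm, covs, selected = c("z1", "z2"))
    oracle <- oracle_reml(y, seg, X[seg, ])
    expect_equal(unname(fit$beta), unname(oracle$beta), tolerance = 1e-5)
    expect_equal(fit$sigma2_e, oracle$s2e, tolerance = 1e-5)
    expect_equal(fit$sigma2_b, oracle$s2b, tolerance = 1e-5)
  }
})

test_that("REML agrees with an independent mixed-model implementation", {
  set.seed(17)
  m <- 40
  n_i <- sample(2:9, m, replace = TRUE)
  z <- rnorm(m)
  y <- rep(5 + 1.5 * z + rnorm(m, 0, 2), n_i) + rnorm(sum(n_i), 0, 1)
  seg <- rep(seq_len(m), n_i)
  pm <- data.frame(segment_id = seg, mean_conc = y)
  fit <- fit_mixed(pm, data.frame(segment_id = seq_len(m), z = z),
                   selected = "z")
  lf <- lme4::lmer(y ~ zz + (1 | s), REML = TRUE,
                   data = data.frame(y = y, zz = z[seg], s = factor(seg)))
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(unname(fit$beta), unname(lme4::fixef(lf)), tolerance = 1e-4)
  expect_equal(fit$sigma2_b, vc$vcov[vc$grp == "s"], tolerance = 1e-3)
  expect_equal(fit$sigma2_e, vc$vcov[vc$grp == "Residual"], tolerance = 1e-3)
  expect_equal(unname(blup(fit, 1:m)), unname(lme4::ranef(lf)$s[, 1]),
               tolerance = 1e-3)
})

test_that("without between-segment heterogeneity the variance ratio hits the boundary", {
  set.seed(18)
  m <- 150
  z <- runif(m)
  n_i <- rep(4, m)
  y <- rep(10 + 2 * z, n_i) + rnorm(sum(n_i), 0, 2)  # b identically zero
  pm <- data.frame(segment_id = rep(seq_len(m), n_i), mean_conc = y)
  fit <- fit_mixed(pm, data.frame(segment_id = seq_len(m), z = z),
                   selected = "z")
  # REML puts sigma2_b at or near zero; predictions collapse to fixed effects
  expect_lt(fit$sigma2_b, 0.2)
  expect_lt(max(abs(fit$segments$pred - fit$segments$fixed_pred)), 0.35)
})

test_that("shrinkage weights rise with pass count and predictions stay between the two surfaces", {
  set.seed(19)
  pm <- simulate_pass_means(200, 7, sigma2_b = 16, sigma2_e = 25)
  fit <- fit_mixed(pm, data.frame(segment_id = unique(pm$segment_id)),
                   selected = character(0))
  s <- fit$segments
  expect_true(all(s$shrink_w >= 0 & s$shrink_w < 1))
  # monotone in n among segments with different pass counts
  ord <- order(s$n_passes)
  expect_true(all(diff(s$shrink_w[ord]) >= -1e-12))
  # convex combination: pred between ybar and the fixed surface
  lo <- pmin(s$ybar, s$fixed_pred) - 1e-9
  hi <- pmax(s$ybar, s$fixed_pred) + 1e-9
  expect_true(all(s$pred >= lo & s$pred <= hi))
  # GLS normal equations: sum_i n_i (ybar - fixed - blup) = 0
  expect_lt(abs(sum(s$n_passes * (s$ybar - s$fixed_pred - s$blup))),
            1e-6 * sum(abs(s$ybar)))
})

test_that("single-pass-only data and thin designs are refused", {
  pm1 <- data.frame(segment_id = 1:5, mean_conc = rnorm(5))
  expect_error(fit_mixed(pm1, data.frame(segment_id = 1:5)),
               "unidentifiable")
  expect_error(fit_mixed(pm1[1:2, ][c(1, 1), ],
                         data.frame(segment_id = 1)),
               "at least 2 segments")
})

test_that("frozen fixed effects keep the supplied coefficients and still estimate variances", {
  set.seed(20)
  pm <- simulate_pass_means(150, 6, sigma2_b = 9, sigma2_e = 16)
  ids <- unique(pm$segment_id)
  frozen_beta <- c("(Intercept)" = 21)
  fit <- fit_mixed(pm, data.frame(segment_id = ids),
                   selected = character(0), freeze_beta = frozen_beta)
  expect_equal(unname(fit$beta), 21)
  expect_gt(fit$sigma2_e, 5)
  expect_gt(fit$sigma2_b, 1)
  expect_error(
    fit_mixed(pm, data.frame(segment_id = ids), selected = character(0),
              freeze_beta = c(foo = 1)),
    "freeze_beta lacks"
  )
})

test_that("the map predicts measured segments with BLUPs and falls back to the LUR surface elsewhere", {
  set.seed(21)
  net <- generate_network(50)
  cfg <- campaign_config(n_segments = 50)
  tr <- generate_truth(net, cfg)
  pm <- simulate_pass_means(40, 5, 9, 16, network = net)  # segments 1..40 only
  pm <- pm[pm$segment_id <= 40, ]
  fit <- fit_mixed(pm, net, selected = "traffic_intensity")
  map <- predict_map(fit, net)
  expect_equal(nrow(map), 50)
  unmeasured <- map$lur_only
  expect_equal(sort(map$segment_id[unmeasured]), 41:50)
  expect_equal(map$mixed_pred[unmeasured], map$lur_pred[unmeasured])
  expect_equal(map$blup[unmeasured], rep(0, sum(unmeasured)))
  expect_equal(map$n_passes[unmeasured], rep(0L, sum(unmeasured)))
  measured <- !unmeasured
  expect_equal(map$mixed_pred[measured],
               map$lur_pred[measured] + map$blup[measured])

  # facade adjustment is a plain scalar on all layers
  map8 <- predict_map(fit, net, facade_adjust = 0.8)
  expect_equal(map8$mixed_pred, 0.8 * map$mixed_pred)
})
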