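test_that("points match their nearest segment within the radius only", {
  net <- two_segment_network(ids = c(1L, 2L))
  pts <- data.frame(id = c("near", "far"), x = c(25, 25), y = c(5.5, 35),
                    value = c(30, 40))
  m <- match_points(pts, net, radius = 20)
  # 5.5 m from segment 1's line (y=10 is 4.5 m away -> segment 2 nearer)
  expect_equal(nrow(m), 1)
  expect_equal(m$external_id, "near")
  expect_equal(m$segment_id, 2L)
  expect_equal(m$ref_value, 30)
  # 25 m from the nearest segment: excluded at radius 20
  m25 <- match_points(data.frame(x = 25, y = 35, value = 1), net, radius = 26)
  expect_equal(nrow(m25), 1)
})

test_that("matching equals the exhaustive all-pairs scan on random instances", {
  set.seed(300)
  for (case in 1:10) {
    net <- random_network(n = sample(6:14, 1))
    pts <- data.frame(x = runif(100, -60, 620), y = runif(100, -60, 620))
    m <- match_points(pts, net, radius = 20)
    got <- rep(NA_integer_, 100)
    got[match(m$external_id, seq_len(100))] <- m$segment_id
    for (i in 1:100) {
      want <- oracle_snap(pts$x[i], pts$y[i], net$segments, 20)
      expect_identical(got[i], want$id)
    }
  }
})

test_that("coordinates that look like longitude/latitude are rejected", {
  net <- two_segment_network()
  pts <- data.frame(x = c(4.8951, 4.8972, 4.8990), y = c(52.3701, 52.3722, 52.3741),
                    value = 1:3)
  expect_error(match_points(pts, net), "degrees")
})

test_that("the metric battery matches hand arithmetic", {
  r <- compute_metrics(c(20, 30), c(25, 33))
  expect_equal(r$rmse, sqrt(17))
  expect_equal(r$mean_bias, 4)
  expect_equal(r$mean_relative_bias, 16)  # 4 / 25 * 100
  expect_equal(r$n, 2)

  mono <- compute_metrics(c(1, 2, 3), c(10, 20, 30))
  expect_equal(mono$r_s, 1)

  same <- compute_metrics(c(5, 7, 9), c(5, 7, 9))
  expect_equal(same$rmse, 0)
  expect_equal(same$mean_bias, 0)
  expect_equal(same$mean_relative_bias, 0)

  expect_error(compute_metrics(1, 2), "at least 2")
})

test_that("swapping reference and test negates bias, preserves RMSE and |r_s|", {
  set.seed(301)
  for (case in 1:50) {
    n <- sample(3:30, 1)
    ref <- runif(n, 10, 50)
    test <- ref + rnorm(n, 2, 5)
    a <- compute_metrics(ref, test)
    b <- compute_metrics(test, ref)
    expect_equal(a$mean_bias, -b$mean_bias)
    expect_equal(a$rmse, b$rmse)
    expect_equal(abs(a$r_s), abs(b$r_s))
  }
})

test_that("Spearman with ties equals rank-then-Pearson to 1e-12", {
  set.seed(302)
  for (case in 1:200) {
    n <- sample(4:40, 1)
    ref <- sample(1:8, n, replace = TRUE) + 0  # heavy ties
    test <- ref + sample(0:3, n, replace = TRUE)
    if (sd(ref) == 0 || sd(test) == 0) next
    expect_equal(compute_metrics(ref, test)$r_s, oracle_spearman(ref, test),
                 tolerance = 1e-12)
  }
})

test_that("five-number summaries use inclusive linear-interpolation quantiles", {
  set.seed(303)
  for (case in 1:50) {
    v <- runif(sample(2:30, 1), 0, 100)
    got <- unlist(segmap:::summary_block(v))
    expect_equal(unname(got), oracle_quantiles(v), tolerance = 1e-12)
  }
})

test_that("Bland-Altman summaries describe the difference distribution", {
  set.seed(304)
  ref <- runif(50, 10, 40)
  test <- ref * 1.1 + rnorm(50, 0, 1)
  r <- compute_metrics(ref, test)
  d <- test - ref
  expect_equal(r$ba_mean, mean(d))
  expect_equal(r$ba_lower, mean(d) - 1.96 * sd(d))
  expect_equal(r$ba_upper, mean(d) + 1.96 * sd(d))
  # proportional bias: difference grows with the pair average
  expect_gt(r$ba_slope, 0)
})

test_that("product comparison emits one report per product and external set", {
  set.seed(305)
  camp <- simulate_campaign(campaign_config(n_segments = 60), seed = 305)
  res <- run_pipeline(camp)
  s <- camp$network$segments
  ext <- data.frame(
    x = s$xm + runif(60, -5, 5), y = s$ym + runif(60, -5, 5),
    value = res$map$mixed_pred
  )
  products <- list(
    data_only = data.frame(segment_id = res$map$segment_id,
                           value = res$map$mean_of_means),
    lur = data.frame(segment_id = res$map$segment_id, value = res$map$lur_pred),
    mixed = data.frame(segment_id = res$map$segment_id,
                       value = res$map$mixed_pred)
  )
  out <- compare_products(products, list(sites = ext), camp$network)
  expect_equal(sort(unique(out$metrics$product)),
               c("data_only", "lur", "mixed"))
  # external set sampled from the mixed map: rank-perfect for mixed
  expect_equal(out$metrics$r_s[out$metrics$product == "mixed"], 1,
               tolerance = 1e-9)
  expect_true(all(out$metrics$rmse >= abs(out$metrics$mean_bias)))
  expect_true("(reference)" %in% out$summary$product)

  expect_warning(empty <- compare_products(products, list(none = ext[0, ]),
                                           camp$network),
                 "empty")
  expect_equal(nrow(empty$metrics), 0)
})
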