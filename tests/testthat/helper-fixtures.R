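# Small in-code fixtures shared across test files.

# two parallel horizontal segments, 10 m apart, ids chosen to exercise
# tie-breaking
two_segment_network <- function(ids = c(1L, 2L)) {
  street_network(
    segments = data.frame(
      segment_id = ids,
      x0 = c(0, 0), y0 = c(0, 10),
      x1 = c(50, 50), y1 = c(0, 10)
    ),
    covariates = data.frame(segment_id = ids)
  )
}

# random small network of axis-aligned 50 m segments for property tests
random_network <- function(n = 12) {
  horiz <- runif(n) < 0.5
  x0 <- round(runif(n, 0, 500))
  y0 <- round(runif(n, 0, 500))
  street_network(
    segments = data.frame(
      segment_id = sample(1000L, n),
      x0 = x0, y0 = y0,
      x1 = x0 + ifelse(horiz, 50, 0),
      y1 = y0 + ifelse(horiz, 0, 50)
    )
  )
}

# drive-pass means simulated straight at the pass level from the
# one-way random-intercept model (no drift, no 1 Hz layer)
simulate_pass_means <- function(n_segments, mean_passes, sigma2_b, sigma2_e,
                                beta = NULL, network = NULL) {
  if (is.null(network)) network <- generate_network(n_segments)
  n_segments <- nrow(network$covariates)
  if (is.null(beta))
    beta <- c("(Intercept)" = 20, traffic_intensity = 0.8,
              population_density = 0.6, port_area = 5)
  covs <- setdiff(names(beta), "(Intercept)")
  X <- as.matrix(network$covariates[, covs, drop = FALSE])
  mu <- drop(beta[["(Intercept)"]] + X %*% beta[covs])
  b <- rnorm(n_segments, 0, sqrt(sigma2_b))
  k <- 1L + rpois(n_segments, mean_passes - 1)
  seg <- rep(seq_len(n_segments), k)
  data.frame(
    segment_id = network$covariates$segment_id[seg],
    pass_date = as.Date("2019-04-01") + sequence(k),
    mean_conc = mu[seg] + b[seg] + rnorm(length(seg), 0, sqrt(sigma2_e))
  )
}
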