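# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: dense matrices instead of per-segment profiling, plain
# loops instead of spatial indexing, rank-then-Pearson instead of
# cor(method = "spearman").

# Dense restricted-likelihood maximiser for the one-way random-intercept
# model: grid over log(lambda) then golden-section refinement, full N x N
# covariance matrix at every evaluation.
oracle_reml <- function(y, seg, X, reml = TRUE,
                        grid = exp(seq(log(1e-8), log(1e8), length.out = 121))) {
  seg <- as.factor(seg)
  Z <- stats::model.matrix(~ seg - 1)
  N <- length(y)
  p <- ncol(X)
  dev_at <- function(lambda) {
    V <- diag(N) + lambda * tcrossprod(Z)
    Vi <- solve(V)
    XtViX <- t(X) %*% Vi %*% X
    beta <- solve(XtViX, t(X) %*% Vi %*% y)
    r <- y - X %*% beta
    Q <- drop(t(r) %*% Vi %*% r)
    df <- if (reml) N - p else N
    s2 <- Q / df
    dev <- df * (log(2 * pi * s2) + 1) +
      determinant(V, logarithm = TRUE)$modulus +
      (if (reml) determinant(XtViX, logarithm = TRUE)$modulus else 0)
    list(dev = as.numeric(dev), beta = drop(beta), s2e = s2, s2b = lambda * s2)
  }
  devs <- vapply(grid, function(l) dev_at(l)$dev, 1)
  i <- which.min(devs)
  lo <- log(grid[max(1, i - 1)])
  hi <- log(grid[min(length(grid), i + 1)])
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- dev_at(exp(c1))$dev; f2 <- dev_at(exp(c2))$dev
  for (it in 1:200) {
    if (f1 < f2) {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- dev_at(exp(c1))$dev
    } else {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- dev_at(exp(c2))$dev
    }
    if (abs(b - a) < 1e-11) break
  }
  best <- dev_at(exp((a + b) / 2))
  at0 <- dev_at(0)
  if (at0$dev <= best$dev) best <- at0
  best
}

# plain point-to-segment distance, scalar
oracle_pt_seg_dist <- function(px, py, x0, y0, x1, y1) {
  dx <- x1 - x0; dy <- y1 - y0
  L2 <- dx^2 + dy^2
  t <- if (L2 > 0) max(0, min(1, ((px - x0) * dx + (py - y0) * dy) / L2)) else 0
  sqrt((px - (x0 + t * dx))^2 + (py - (y0 + t * dy))^2)
}

# nearest segment by looping over all segments; ties to smaller id
oracle_snap <- function(px, py, segs, max_dist) {
  d <- vapply(seq_len(nrow(segs)), function(j)
    oracle_pt_seg_dist(px, py, segs$x0[j], segs$y0[j], segs$x1[j], segs$y1[j]),
    1)
  dmin <- min(d)
  if (dmin > max_dist) return(list(id = NA_integer_, dist = NA_real_))
  list(id = min(segs$segment_id[d == dmin]), dist = dmin)
}

oracle_spearman <- function(x, y) {
  stats::cor(rank(x, ties.method = "average"), rank(y, ties.method = "average"))
}

# type-7 quantiles from first principles on the sorted array
oracle_quantiles <- function(v, probs = c(0, 0.25, 0.5, 0.75, 1)) {
  sv <- sort(v)
  n <- length(sv)
  vapply(probs, function(p) {
    h <- (n - 1) * p
    lo <- floor(h)
    if (lo + 1 >= n) sv[n] else sv[lo + 1] + (h - lo) * (sv[lo + 2] - sv[lo + 1])
  }, 1)
}

# independent supervised forward-stepwise path: exhaustive candidate scan
# at each step with hand-rolled OLS (QR), sign admissibility and adjusted
# R-squared computed from scratch
oracle_stepwise <- function(y, X, signs, gain_min = 0.01) {
  n <- length(y)
  adj <- function(vars) {
    M <- cbind(1, X[, vars, drop = FALSE])
    fit <- qr(M)
    res <- y - M %*% qr.coef(fit, y)
    r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
    k <- length(vars)
    list(adj = 1 - (1 - r2) * (n - 1) / (n - 1 - k),
         beta = drop(qr.coef(fit, y)))
  }
  sel <- character(0)
  cur <- adj(sel)$adj
  path <- character(0)
  repeat {
    rem <- setdiff(colnames(X), sel)
    if (!length(rem)) break
    cand_adj <- rep(-Inf, length(rem))
    names(cand_adj) <- rem
    for (v in rem) {
      a <- adj(c(sel, v))
      b <- a$beta[-1]
      names(b) <- c(sel, v)
      if (anyNA(b)) next
      if (any(sign(b) != signs[names(b)])) next
      cand_adj[v] <- a$adj
    }
    best <- names(cand_adj)[which.max(cand_adj)]
    if (!is.finite(max(cand_adj)) || max(cand_adj) - cur < gain_min) break
    sel <- c(sel, best)
    cur <- max(cand_adj)
    path <- sel
  }
  sel
}
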