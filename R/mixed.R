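#' Fit the random-intercept mixed model on drive-pass means
#'
#' The mapping model behind the mixed map: for drive-pass mean k on
#' segment i,
#'
#' `y_ik = x_i' beta + b_i + e_ik`,  `b_i ~ N(0, sigma2_b)`,
#' `e_ik ~ N(0, sigma2_e)`,
#'
#' with segment-constant covariates `x_i` (typically the LUR-selected set)
#' as fixed effects and one random intercept per street segment. Because
#' the random structure is a single intercept with segment-constant
#' covariates, the restricted likelihood profiles analytically: for each
#' variance ratio `lambda = sigma2_b / sigma2_e` the GLS fixed effects and
#' the residual variance have closed forms built from per-segment weights
#' `w_i = n_i / (1 + lambda * n_i)`, and the fit reduces to a safeguarded
#' one-dimensional search over `log(lambda)` (Brent on
#' `[1e-8, 1e8]` with an explicit boundary check at `lambda = 0`). No
#' N x N matrix is ever formed, so city-scale campaigns fit in
#' milliseconds.
#'
#' REML is the default criterion (its variance components are unbiased for
#' the fixed-effect degrees of freedom, and they drive the shrinkage
#' weights); set `reml = FALSE` for ML. `freeze_beta` instead keeps the
#' fixed effects at externally supplied coefficients (e.g. a [fit_lur()]
#' result) and estimates only the variance components.
#'
#' When the pass means are fitted perfectly by the fixed effects (zero
#' residual, as in noise-free simulations) both variance components are
#' returned as 0 and the fit is flagged `degenerate`.
#'
#' @param pass_means drive-pass means from [aggregate_passes()]
#'   (`segment_id`, `mean_conc`; `pass_date` is not used by the model).
#' @param covariates a `street_network` or covariate data.frame keyed by
#'   `segment_id`, constant within segment.
#' @param selected character vector of fixed-effect covariate names
#'   (besides the always-present intercept); typically `fit$selected` from
#'   [fit_lur()]. Empty means intercept-only.
#' @param reml use restricted maximum likelihood (default) or ML.
#' @param freeze_beta optional `lur_fit` or named coefficient vector; if
#'   given, fixed effects are frozen at these values and only the variance
#'   components are estimated.
#' @param lambda_range search range for the variance ratio.
#' @return Object of class `mixed_fit`: `beta`, `se_beta`, `sigma2_b`,
#'   `sigma2_e`, `lambda`, `logLik` (restricted log-likelihood at the
#'   optimum), `reml`, `degenerate`, `n_obs`, and a per-segment data.frame
#'   `segments` with `segment_id`, `n_passes`, `ybar`, `fixed_pred`
#'   (`x_i' beta`), `shrink_w` (`n_i sigma2_b / (sigma2_e + n_i sigma2_b)`),
#'   `blup` and `pred` (`fixed_pred + blup`).
#' @examples
#' pm <- data.frame(segment_id = c("A", "A", "B", "B"),
#'                  mean_conc = c(1, 3, 5, 7))
#' covs <- data.frame(segment_id = c("A", "B"))
#' fit <- fit_mixed(pm, covs, selected = character(0))
#' c(fit$beta, fit$sigma2_e, fit$sigma2_b)
#' @export
fit_mixed <- function(pass_means, covariates, selected = character(0),
                      reml = TRUE, freeze_beta = NULL,
                      lambda_range = c(1e-8, 1e8)) {
  if (inherits(covariates, "street_network")) covariates <- covariates$covariates

  dt <- data.table::as.data.table(pass_means)
  seg <- dt[, .(n = .N, ybar = mean(mean_conc),
                ssw = sum((mean_conc - mean(mean_conc))^2)),
            by = segment_id]
  data.table::setorder(seg, segment_id)
  m <- nrow(seg)
  n_i <- seg$n
  ybar <- seg$ybar
  SSW <- sum(seg$ssw)
  N <- sum(n_i)
  if (m < 2) stop("need at least 2 segments with measurements")
  if (all(n_i < 2))
    stop("within-segment variance is unidentifiable: every segment has a ",
         "single drive-pass")

  Xc <- covariate_matrix(covariates, selected, seg$segment_id)
  X <- cbind("(Intercept)" = 1, Xc)

  frozen <- !is.null(freeze_beta)
  if (frozen) {
    fb <- if (inherits(freeze_beta, "lur_fit")) freeze_beta$coefficients
          else freeze_beta
    miss <- setdiff(colnames(X), names(fb))
    if (length(miss))
      stop("freeze_beta lacks coefficient(s): ", paste(miss, collapse = ", "))
    beta_fix <- fb[colnames(X)]
    fixed_fix <- drop(X %*% beta_fix)
  }
  p <- if (frozen) 0L else ncol(X)
  df <- if (reml) N - p else N

  # profiled -2 * (restricted) log-likelihood at variance ratio lambda;
  # returns the deviance plus, on request, the GLS pieces at that lambda
  prof <- function(lambda, pieces = FALSE) {
    w <- n_i / (1 + lambda * n_i)
    if (frozen) {
      beta <- beta_fix
      r <- ybar - fixed_fix
      ldXtWX <- 0
    } else {
      XtWX <- crossprod(X * w, X)
      beta <- drop(solve(XtWX, crossprod(X * w, ybar)))
      r <- ybar - drop(X %*% beta)
      ldXtWX <- if (reml) determinant(XtWX, logarithm = TRUE)$modulus else 0
    }
    Q <- SSW + sum(w * r^2)
    s2e <- Q / df
    dev <- df * (log(2 * pi * s2e) + 1) + sum(log1p(lambda * n_i)) +
      (if (reml) ldXtWX else 0)
    if (!pieces) return(as.numeric(dev))
    list(dev = as.numeric(dev), beta = beta, r = r, w = w, Q = Q, s2e = s2e)
  }

  # degenerate perfect fit: zero residual variation at lambda = 0
  at0 <- prof(0, pieces = TRUE)
  scale0 <- max(1, sum(ybar^2))
  if (at0$Q <= 1e-12 * scale0) {
    beta <- if (frozen) beta_fix else at0$beta
    fixed <- drop(X %*% beta)
    segs <- data.frame(segment_id = seg$segment_id, n_passes = n_i,
                       ybar = ybar, fixed_pred = fixed, shrink_w = 0,
                       blup = 0, pred = fixed)
    return(structure(
      list(beta = beta, se_beta = rep(NA_real_, ncol(X)),
           sigma2_b = 0, sigma2_e = 0, lambda = 0, logLik = NA_real_,
           reml = reml, frozen = frozen, degenerate = TRUE,
           n_obs = N, selected = selected, segments = segs),
      class = "mixed_fit"))
  }

  opt <- optimize(function(ll) prof(exp(ll)), interval = log(lambda_range),
                  tol = 1e-9)
  lambda <- exp(opt$minimum)
  dev <- opt$objective
  if (at0$dev <= dev) {  # boundary: no between-segment variance
    lambda <- 0
    dev <- at0$dev
  }
  if (!is.finite(dev))
    stop("restricted likelihood is not finite at the optimum (lambda = ",
         signif(lambda, 4), ", Q = ", signif(prof(lambda, TRUE)$Q, 4), ")")

  at <- prof(lambda, pieces = TRUE)
  s2e <- at$s2e
  s2b <- lambda * s2e
  beta <- at$beta
  se_beta <- if (frozen) rep(NA_real_, ncol(X)) else
    sqrt(diag(solve(crossprod(X * at$w, X))) * s2e)
  shrink <- lambda * n_i / (1 + lambda * n_i)  # = n_i s2b / (s2e + n_i s2b)
  blup <- shrink * at$r
  fixed <- if (frozen) fixed_fix else drop(X %*% at$beta)
  segs <- data.frame(segment_id = seg$segment_id, n_passes = n_i,
                     ybar = ybar, fixed_pred = fixed, shrink_w = shrink,
                     blup = blup, pred = fixed + blup)
  structure(
    list(beta = setNames(as.numeric(beta), colnames(X)),
         se_beta = setNames(se_beta, colnames(X)),
         sigma2_b = s2b, sigma2_e = s2e, lambda = lambda,
         logLik = -dev / 2, reml = reml, frozen = frozen,
         degenerate = FALSE, n_obs = N, selected = selected,
         segments = segs),
    class = "mixed_fit"
  )
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat("<mixed_fit> ", nrow(x$segments), " segments, ", x$n_obs,
      " drive-passes; ", if (x$reml) "REML" else "ML",
      if (x$frozen) " (frozen fixed effects)", "\n",
      "  sigma2_b = ", signif(x$sigma2_b, 4),
      ", sigma2_e = ", signif(x$sigma2_e, 4), "\n", sep = "")
  print(x$beta)
  invisible(x)
}

#' Best linear unbiased predictor of a segment's random intercept
#'
#' The conditional mean of the segment deviation under the fitted model:
#' `b_i = [n_i sigma2_b / (sigma2_e + n_i sigma2_b)] * (ybar_i - x_i' beta)`
#' -- the observed deviation of the segment mean from the fixed-effects
#' surface, shrunk toward zero by a factor that grows with the number of
#' drive-passes.
#'
#' @param fit a [fit_mixed()] result.
#' @param segment_id segment identifier(s) present in the fit.
#' @return numeric BLUP value(s), ug/m3.
#' @export
blup <- function(fit, segment_id) {
  idx <- match(segment_id, fit$segments$segment_id)
  if (anyNA(idx))
    stop("unknown segment id(s): ",
         paste(head(segment_id[is.na(idx)], 5), collapse = ", "))
  fit$segments$blup[idx]
}

#' Predict the mixed map over a street network
#'
#' Measured segments get the mixed-model prediction
#' `x_i' beta + blup_i` -- a convex combination of the segment's own mean
#' and the fixed-effects (LUR) surface. Segments without measurements fall
#' back to the fixed-effects surface alone and are flagged `lur_only`.
#'
#' @param fit a [fit_mixed()] result.
#' @param network a `street_network` (or covariate data.frame) covering the
#'   segments to predict; must contain the fitted covariates.
#' @param facade_adjust optional scalar multiplier applied to all
#'   predictions (e.g. 0.8 to translate on-road levels to building-facade
#'   levels); default 1 (off).
#' @return data.frame with `segment_id`, `lur_pred` (fixed-effects
#'   surface), `blup`, `mixed_pred`, `n_passes`, `shrink_w`, `lur_only`.
#' @export
predict_map <- function(fit, network, facade_adjust = 1) {
  covariates <- if (inherits(network, "street_network")) network$covariates
                else network
  X <- cbind(1, covariate_matrix(covariates, fit$selected))
  fixed <- drop(X %*% fit$beta)
  idx <- match(covariates$segment_id, fit$segments$segment_id)
  measured <- !is.na(idx)
  b <- ifelse(measured, fit$segments$blup[idx], 0)
  out <- data.frame(
    segment_id = covariates$segment_id,
    lur_pred = facade_adjust * fixed,
    blup = facade_adjust * b,
    mixed_pred = facade_adjust * (fixed + b),
    n_passes = ifelse(measured, fit$segments$n_passes[idx], 0L),
    shrink_w = ifelse(measured, fit$segments$shrink_w[idx], NA_real_),
    lur_only = !measured
  )
  out
}
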