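#' Fit a supervised forward-stepwise land-use regression
#'
#' Regresses per-segment long-term concentrations (mean of drive-pass
#' means) on segment covariates with supervised forward selection, the
#' convention used throughout the LUR exposure-assessment literature:
#'
#' * at each step the candidate giving the largest adjusted R-squared is
#'   entered, provided its coefficient has the expected sign, no previously
#'   entered coefficient flips sign, and the adjusted R-squared gain is at
#'   least `gain_min`;
#' * after selection, covariates with p >= `p_remove` (or a sign violated
#'   in the refit) are removed and the final OLS refitted until stable.
#'
#' The intercept is always included and exempt from sign constraints. OLS
#' is unweighted over segments (pass counts do not weight the fit).
#'
#' @param summaries data-only map from [summarize_segments()]
#'   (`segment_id`, `mean_of_means`), or any data.frame with those columns.
#' @param covariates a `street_network` (covariates and expected signs are
#'   taken from it) or a covariate data.frame keyed by `segment_id`.
#' @param expected_sign named vector of +1/-1 expected coefficient signs;
#'   required when `covariates` is a bare data.frame. Its names define the
#'   candidate set.
#' @param gain_min minimum adjusted R-squared gain to enter a covariate.
#' @param p_remove significance level above which an entered covariate is
#'   dropped after selection.
#' @return Object of class `lur_fit`: selected names (entry order),
#'   `coefficients`, per-segment `fitted` (named by segment id), `r2`,
#'   `adj_r2`, `p_values`, selection `path`, `n`.
#' @examples
#' set.seed(7)
#' z <- runif(40)
#' summ <- data.frame(segment_id = 1:40, mean_of_means = 10 + 2 * z)
#' fit <- fit_lur(summ, data.frame(segment_id = 1:40, z = z),
#'                expected_sign = c(z = 1))
#' coef(fit)
#' @export
fit_lur <- function(summaries, covariates, expected_sign = NULL,
                    gain_min = 0.01, p_remove = 0.10) {
  if (inherits(covariates, "street_network")) {
    if (is.null(expected_sign)) expected_sign <- covariates$expected_sign
    covariates <- covariates$covariates
  }
  if (is.null(expected_sign) || is.null(names(expected_sign)))
    stop("`expected_sign` must be a named vector of +1/-1")
  candidates <- names(expected_sign)
  y <- summaries$mean_of_means
  X <- covariate_matrix(covariates, candidates, summaries$segment_id)
  n <- length(y)
  if (n < length(candidates) + 2)
    stop("need at least p + 2 segments to fit ", length(candidates),
         " candidate covariates")

  dat <- data.frame(y = y, X, check.names = FALSE)

  fit_ols <- function(vars) {
    f <- if (length(vars)) stats::reformulate(sprintf("`%s`", vars), "y")
         else y ~ 1
    stats::lm(f, data = dat)
  }
  # perfect fits are legitimate here (noise-free simulations); summary.lm
  # warns about them, and coef_p maps their NaN p-values to 0
  smry <- function(fit) suppressWarnings(summary(fit))
  adj_r2 <- function(fit) smry(fit)$adj.r.squared
  coef_p <- function(fit) {
    sm <- smry(fit)$coefficients
    p <- sm[, 4]
    p[is.nan(p)] <- 0  # perfect fit: zero residual variance
    p
  }
  norm_coef <- function(fit) {
    b <- coef(fit)
    names(b) <- gsub("`", "", names(b))
    b
  }
  sign_ok <- function(fit, vars) {
    if (!length(vars)) return(TRUE)
    b <- norm_coef(fit)[vars]
    !anyNA(b) && all(sign(b) == expected_sign[vars])
  }

  selected <- character(0)
  current <- fit_ols(selected)
  current_adj <- adj_r2(current)
  path <- data.frame(step = 0L, added = "(Intercept)", adj_r2 = current_adj)

  repeat {
    remaining <- setdiff(candidates, selected)
    if (!length(remaining)) break
    best <- NULL
    best_adj <- -Inf
    for (v in remaining) {
      fit <- fit_ols(c(selected, v))
      if (fit$rank < length(selected) + 2L) next  # collinear addition
      if (!sign_ok(fit, c(selected, v))) next     # sign constraint incl. flips
      a <- adj_r2(fit)
      if (a > best_adj) {
        best <- v
        best_adj <- a
      }
    }
    if (is.null(best) || best_adj - current_adj < gain_min) {
      if (!length(selected) && !is.null(gain_min))
        if (is.null(best)) warning("no admissible covariate at step 1; ",
                                   "returning intercept-only model")
      break
    }
    selected <- c(selected, best)
    current_adj <- best_adj
    path <- rbind(path, data.frame(step = length(selected), added = best,
                                   adj_r2 = best_adj))
  }

  # backward cleanup: drop insignificant or sign-violating covariates,
  # refit until stable (order of entry preserved among survivors)
  repeat {
    current <- fit_ols(selected)
    if (!length(selected)) break
    b_all <- norm_coef(current)
    if (anyNA(b_all))
      stop("design matrix is rank deficient; collinear column(s): ",
           paste(names(b_all)[is.na(b_all)], collapse = ", "))
    p <- coef_p(current)
    names(p) <- names(b_all)
    drop <- selected[p[selected] >= p_remove |
                       sign(b_all[selected]) != expected_sign[selected]]
    if (!length(drop)) break
    selected <- setdiff(selected, drop)
  }

  sm <- smry(current)
  beta <- norm_coef(current)
  pv <- coef_p(current)
  names(pv) <- names(beta)

  # fitted values recomputed as x'beta so they agree bitwise with
  # predict_lur() on the training covariates
  Xsel <- X[, selected, drop = FALSE]
  fitted_xb <- rep(beta[["(Intercept)"]], n) +
    (if (length(selected)) drop(Xsel %*% beta[selected]) else 0)

  structure(
    list(selected = selected,
         coefficients = beta,
         fitted = setNames(fitted_xb, summaries$segment_id),
         r2 = sm$r.squared,
         adj_r2 = sm$adj.r.squared,
         p_values = pv,
         path = path,
         expected_sign = expected_sign,
         gain_min = gain_min, p_remove = p_remove,
         n = n),
    class = "lur_fit"
  )
}

#' @export
coef.lur_fit <- function(object, ...) object$coefficients

#' @export
print.lur_fit <- function(x, ...) {
  cat("<lur_fit> ", length(x$selected), " covariate(s) selected of ",
      length(x$expected_sign), " candidates; R2 = ", signif(x$r2, 3),
      ", adj R2 = ", signif(x$adj_r2, 3), ", n = ", x$n, "\n", sep = "")
  print(x$coefficients)
  invisible(x)
}

#' Predict from a fitted land-use regression
#'
#' Deterministic fixed-effects surface `x_i' beta` for any segments with
#' the selected covariates available.
#'
#' @param fit a [fit_lur()] result.
#' @param covariates a `street_network` or covariate data.frame containing
#'   every selected covariate (an error names any missing column).
#' @return numeric predictions named by `segment_id`.
#' @export
predict_lur <- function(fit, covariates) {
  if (inherits(covariates, "street_network")) covariates <- covariates$covariates
  X <- covariate_matrix(covariates, fit$selected)
  beta <- fit$coefficients
  pred <- rep(beta[["(Intercept)"]], nrow(covariates)) +
    (if (length(fit$selected)) drop(X %*% beta[fit$selected]) else 0)
  setNames(as.numeric(pred), covariates$segment_id)
}

#' @export
predict.lur_fit <- function(object, newdata, ...) predict_lur(object, newdata)
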