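#' Match external monitoring points to their nearest street segments
#'
#' For each external point (e.g. a passive-sampler site or a dispersion
#' model receptor) finds the nearest street segment by polyline distance;
#' points farther than `radius` metres from every segment are excluded.
#' Exact ties go to the smaller `segment_id`. Both inputs must be in the
#' same planar metric coordinates; inputs whose coordinates look like
#' geographic degrees are rejected rather than silently mismatched.
#'
#' @param points data.frame with `x`, `y` and optionally `id` (defaults to
#'   row number) and `value` (the reference concentration).
#' @param network a `street_network`.
#' @param values optional named vector or data.frame (`segment_id`,
#'   `value`) giving the map value per segment to attach as `test_value`.
#' @param radius maximum matching distance in metres (default 20).
#' @return data.frame of `MatchedPairs`: `external_id`, `segment_id`,
#'   `distance`, plus `ref_value` / `test_value` where available.
#' @export
match_points <- function(points, network, values = NULL, radius = 20) {
  looks_degrees <- function(x, y) {
    length(x) > 1 &&
      all(abs(x) <= 180) && all(abs(y) <= 90) &&
      diff(range(x)) < 5 && diff(range(y)) < 5 &&
      any(x != round(x) | y != round(y))
  }
  s <- network$segments
  if (looks_degrees(points$x, points$y) ||
      looks_degrees(c(s$x0, s$x1), c(s$y0, s$y1)))
    stop("coordinates look like geographic degrees; supply projected ",
         "planar coordinates in metres")

  seg <- snap_to_segment(points[, c("x", "y")], network, max_dist = radius)
  keep <- !is.na(seg)
  out <- data.frame(
    external_id = (points$id %||% seq_len(nrow(points)))[keep],
    segment_id = seg[keep],
    distance = attr(seg, "distance")[keep]
  )
  if (!is.null(points$value)) out$ref_value <- points$value[keep]
  if (!is.null(values)) {
    if (is.data.frame(values))
      values <- setNames(values$value, values$segment_id)
    out$test_value <- as.numeric(values[as.character(out$segment_id)])
  }
  out
}

#' Validation metrics for one map product against one reference set
#'
#' The comparison battery for matched (reference, map) pairs: Spearman rank
#' correlation (average ranks on ties), RMSE, mean bias, mean relative
#' bias, and a Bland-Altman summary (mean difference, 95% limits of
#' agreement, slope of difference against pair average).
#'
#' Bias convention: `mean_bias = mean(test - ref)`, i.e. positive when the
#' map product exceeds the external reference data; the convention is
#' recorded in the report so tables are self-describing. Relative bias is
#' the mean bias as a percentage of the mean reference value over the
#' matched pairs.
#'
#' @param pairs a [match_points()] result with `ref_value` and
#'   `test_value`, or a numeric vector of reference values.
#' @param test numeric map values when `pairs` is a vector.
#' @return list of class `metric_report`: `n`, `r_s`, `rmse`, `mean_bias`,
#'   `mean_relative_bias` (percent), `ba_mean`, `ba_lower`, `ba_upper`,
#'   `ba_slope`, `bias_convention`.
#' @examples
#' compute_metrics(c(20, 30), c(25, 33))$rmse  # sqrt(17)
#' @export
compute_metrics <- function(pairs, test = NULL) {
  if (is.data.frame(pairs)) {
    ref <- pairs$ref_value
    test <- pairs$test_value
  } else {
    ref <- pairs
  }
  ok <- is.finite(ref) & is.finite(test)
  ref <- ref[ok]
  test <- test[ok]
  n <- length(ref)
  if (n < 2) stop("need at least 2 matched pairs, got ", n)
  d <- test - ref
  avg <- (test + ref) / 2
  slope <- if (n >= 3 && var(avg) > 0) unname(coef(lm(d ~ avg))[2]) else NA_real_
  structure(
    list(n = n,
         r_s = if (sd(ref) > 0 && sd(test) > 0)
                 cor(ref, test, method = "spearman") else NA_real_,
         rmse = sqrt(mean(d^2)),
         mean_bias = mean(d),
         mean_relative_bias = 100 * mean(d) / mean(ref),
         ba_mean = mean(d),
         ba_lower = mean(d) - 1.96 * sd(d),
         ba_upper = mean(d) + 1.96 * sd(d),
         ba_slope = slope,
         bias_convention = "mean(test - ref): positive when the map product exceeds the reference"),
    class = "metric_report"
  )
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report> n = ", x$n,
      ", r_s = ", signif(x$r_s, 3),
      ", RMSE = ", signif(x$rmse, 3),
      ", mean bias = ", signif(x$mean_bias, 3),
      " (", signif(x$mean_relative_bias, 3), "%)\n", sep = "")
  invisible(x)
}

# five-number summary, linear-interpolation (type 7) quantiles
summary_block <- function(v) {
  q <- quantile(v, c(0, 0.25, 0.5, 0.75, 1), type = 7, names = FALSE)
  setNames(as.list(q), c("min", "q1", "median", "q3", "max"))
}

#' Compare map products against external datasets
#'
#' Runs the full validation table: every map product (typically data-only,
#' LUR and mixed) against every external point set, each matched to its
#' nearest segment within `radius` metres, with the metric battery of
#' [compute_metrics()] and a five-number summary block per row (external
#' reference values and matched map values), mirroring how such
#' comparisons are tabulated.
#'
#' @param products named list of map layers; each a data.frame with
#'   `segment_id` and `value`, or a named vector keyed by segment id.
#' @param external_sets named list of external point data.frames (`x`,
#'   `y`, `value`, optional `id`).
#' @param network the `street_network` the maps live on.
#' @param radius matching radius in metres (default 20).
#' @return list with `metrics` (long data.frame: `external`, `product`,
#'   `n`, `r_s`, `rmse`, `mean_bias`, `mean_relative_bias`) and `summary`
#'   (five-number blocks per external set and product). Empty external
#'   sets yield zero rows with a warning.
#' @export
compare_products <- function(products, external_sets, network, radius = 20) {
  stopifnot(length(names(products)) == length(products),
            length(names(external_sets)) == length(external_sets))
  as_named <- function(p) {
    if (is.data.frame(p)) setNames(p$value, p$segment_id) else p
  }
  metrics <- list()
  summaries <- list()
  for (ename in names(external_sets)) {
    ext <- external_sets[[ename]]
    if (is.null(ext) || nrow(ext) == 0) {
      warning("external set '", ename, "' is empty; skipping")
      next
    }
    matched <- match_points(ext, network, radius = radius)
    if (nrow(matched) == 0) {
      warning("external set '", ename, "' has no points within ", radius,
              " m of the network; skipping")
      next
    }
    summaries[[paste(ename, "reference", sep = ".")]] <-
      data.frame(external = ename, product = "(reference)",
                 summary_block(matched$ref_value))
    for (pname in names(products)) {
      vals <- as_named(products[[pname]])
      test <- as.numeric(vals[as.character(matched$segment_id)])
      rep <- compute_metrics(matched$ref_value, test)
      metrics[[paste(ename, pname)]] <- data.frame(
        external = ename, product = pname, n = rep$n, r_s = rep$r_s,
        rmse = rep$rmse, mean_bias = rep$mean_bias,
        mean_relative_bias = rep$mean_relative_bias
      )
      summaries[[paste(ename, pname, sep = ".")]] <-
        data.frame(external = ename, product = pname, summary_block(test))
    }
  }
  empty_m <- data.frame(external = character(), product = character(),
                        n = integer(), r_s = numeric(), rmse = numeric(),
                        mean_bias = numeric(), mean_relative_bias = numeric())
  list(
    metrics = if (length(metrics)) do.call(rbind, c(metrics, make.row.names = FALSE)) else empty_m,
    summary = if (length(summaries)) do.call(rbind, c(summaries, make.row.names = FALSE)) else
      data.frame(external = character(), product = character())
  )
}
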