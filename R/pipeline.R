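#' Run the full mapping pipeline on a campaign
#'
#' Chains every stage from raw 1 Hz records to the three map products:
#' range filtering, (optional) geometric snapping to the street network,
#' temporal correction against the reference station, aggregation to
#' drive-pass means and the per-segment mean of means (data-only map),
#' supervised stepwise LUR on the mean of means, and the random-intercept
#' mixed model on all drive-pass means with the LUR-selected covariates.
#'
#' @param campaign a [simulate_campaign()] result, or a list with elements
#'   `measurements`, `network`, `reference`.
#' @param snap if `TRUE`, re-derive segment assignment geometrically with
#'   [snap_to_segment()]; if `FALSE` (default) use the `segment_id` column
#'   already present on the records (as the synthetic generator provides).
#' @param max_dist snapping distance cap, metres.
#' @param correct apply temporal correction (default `TRUE`).
#' @param granularity,method temporal-correction options, see
#'   [build_window_table()] and [correct_temporal()].
#' @param gain_min,p_remove LUR stepwise options, see [fit_lur()].
#' @param freeze_beta if `TRUE`, the mixed model keeps the LUR coefficients
#'   frozen instead of re-estimating the fixed effects (default re-fit).
#' @param facade_adjust optional scalar for [predict_map()].
#' @return list of class `segmap_result`: filtered/corrected
#'   `measurements`, `window_table`, `pass_means`, `data_only` (segment
#'   summaries), `lur` fit, `mixed` fit, and the combined `map`
#'   (data-only, LUR and mixed columns per segment).
#' @export
run_pipeline <- function(campaign, snap = FALSE, max_dist = 50,
                         correct = TRUE,
                         granularity = "hour_weekday", method = "additive",
                         gain_min = 0.01, p_remove = 0.10,
                         freeze_beta = FALSE, facade_adjust = 1) {
  meas <- filter_range(campaign$measurements)
  if (snap || is.null(meas$segment_id)) {
    sid <- snap_to_segment(meas[, c("x", "y")], campaign$network, max_dist)
    meas$segment_id <- as.integer(sid)
  }
  wt <- NULL
  if (correct) {
    wt <- build_window_table(campaign$reference, granularity)
    meas <- correct_temporal(meas, wt, method)
  }
  pm <- aggregate_passes(meas)
  ds <- summarize_segments(pm)
  lur <- fit_lur(ds, campaign$network, gain_min = gain_min,
                 p_remove = p_remove)
  mix <- fit_mixed(pm, campaign$network, selected = lur$selected,
                   freeze_beta = if (freeze_beta) lur else NULL)
  map <- predict_map(mix, campaign$network, facade_adjust = facade_adjust)
  map$mean_of_means <- ds$mean_of_means[match(map$segment_id, ds$segment_id)]
  map$sem <- ds$sem[match(map$segment_id, ds$segment_id)]
  structure(
    list(measurements = meas, window_table = wt, pass_means = pm,
         data_only = ds, lur = lur, mixed = mix, map = map),
    class = "segmap_result"
  )
}

#' @export
print.segmap_result <- function(x, ...) {
  cat("<segmap_result> ", nrow(x$map), " segments mapped (",
      sum(!x$map$lur_only), " measured); LUR adj R2 = ",
      signif(x$lur$adj_r2, 3), "; sigma2_b = ", signif(x$mixed$sigma2_b, 4),
      ", sigma2_e = ", signif(x$mixed$sigma2_e, 4), "\n", sep = "")
  invisible(x)
}
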