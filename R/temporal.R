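#' Map timestamps to temporal-correction windows
#'
#' Window granularities: `"hour_weekday"` (hour-of-day x day-of-week, the
#' default -- with weekday daytime-only mobile sampling this is 14 hourly
#' bins per weekday), `"hour_weekpart"` (hour x weekday/weekend) and
#' `"hour"` (hour-of-day only).
#'
#' @param t POSIXct timestamps (UTC).
#' @param granularity window definition.
#' @return character window keys, one per timestamp.
#' @export
window_key <- function(t, granularity = c("hour_weekday", "hour_weekpart", "hour")) {
  granularity <- match.arg(granularity)
  lt <- as.POSIXlt(t, tz = "UTC")
  h <- sprintf("h%02d", lt$hour)
  wd <- ((lt$wday + 6L) %% 7L) + 1L
  switch(granularity,
    hour_weekday = paste0("wd", wd, "_", h),
    hour_weekpart = paste0(ifelse(wd <= 5L, "wk_", "we_"), h),
    hour = h
  )
}

#' Build the reference-station time-window table
#'
#' For each time window, the mean reference concentration over the campaign;
#' plus the overall mean of the full reference series (all hours of all
#' days, not a mean of window means -- the reference runs day and night, so
#' the overall mean is the long-term level that corrected mobile data
#' should reflect).
#'
#' @param reference data.frame with `timestamp`, `no2_ugm3` at a fixed
#'   cadence.
#' @param granularity passed to [window_key()].
#' @return data.frame of class `window_table` (`window`, `ref_mean`,
#'   `n_obs`) with attributes `overall_mean` and `granularity`.
#' @export
build_window_table <- function(reference,
                               granularity = c("hour_weekday", "hour_weekpart", "hour")) {
  granularity <- match.arg(granularity)
  if (nrow(reference) == 0) stop("empty reference series")
  if (anyNA(reference$no2_ugm3)) stop("reference series contains NA values")
  key <- window_key(reference$timestamp, granularity)
  dt <- data.table::data.table(window = key, v = reference$no2_ugm3)
  tab <- dt[, .(ref_mean = mean(v), n_obs = .N), by = window]
  data.table::setorder(tab, window)
  data.table::setDF(tab)
  structure(tab, overall_mean = mean(reference$no2_ugm3),
            granularity = granularity,
            class = c("window_table", "data.frame"))
}

#' Correct mobile measurements for sampling time
#'
#' Removes the temporal sampling bias of a mobile campaign using the
#' reference station: each record measured in window w becomes
#'
#' `corrected = measured + (overall_mean - ref_mean_w)` (additive, default)
#'
#' or `measured * overall_mean / ref_mean_w` (`method = "ratio"`). A record
#' whose window is absent from the table is an error -- there is no silent
#' fallback.
#'
#' @param records data.frame with `timestamp` and the concentration column
#'   `no2_ugm3`.
#' @param table a [build_window_table()] result.
#' @param method additive (difference) or ratio correction.
#' @return `records` with `no2_ugm3` replaced by the corrected value and
#'   the original retained as `no2_uncorrected`.
#' @export
correct_temporal <- function(records, table, method = c("additive", "ratio")) {
  method <- match.arg(method)
  key <- window_key(records$timestamp, attr(table, "granularity"))
  idx <- match(key, table$window)
  if (anyNA(idx)) {
    miss <- unique(key[is.na(idx)])
    stop("no reference data for time window(s): ",
         paste(head(miss, 5), collapse = ", "))
  }
  overall <- attr(table, "overall_mean")
  wmean <- table$ref_mean[idx]
  records$no2_uncorrected <- records$no2_ugm3
  records$no2_ugm3 <- switch(method,
    additive = records$no2_ugm3 + (overall - wmean),
    ratio = records$no2_ugm3 * overall / wmean
  )
  records
}
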