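#' Remove physically implausible concentration records
#'
#' Drops records with concentrations below `lower` or above `upper`
#' (defaults 0 and 500 ug/m3); values exactly on a bound are kept. Order is
#' preserved and the number removed at each bound is attached as the
#' `"removed"` attribute (and reported via [filter_removed()]).
#'
#' @param records data.frame of measurement records, or a numeric vector of
#'   concentrations.
#' @param lower,upper inclusive retention bounds, ug/m3.
#' @param col name of the concentration column when `records` is a
#'   data.frame.
#' @return The retained records (same type as the input) with attribute
#'   `removed = c(low = , high = )`.
#' @examples
#' kept <- filter_range(c(-5, 0, 10, 500, 500.1))
#' filter_removed(kept)  # one low, one high
#' @export
filter_range <- function(records, lower = 0, upper = 500, col = "no2_ugm3") {
  v <- if (is.data.frame(records)) {
    if (!col %in% names(records)) stop("no column `", col, "` in records")
    records[[col]]
  } else {
    records
  }
  low <- v < lower
  high <- v > upper
  keep <- !(low | high)
  out <- if (is.data.frame(records)) records[keep, , drop = FALSE] else records[keep]
  if (is.data.frame(out)) rownames(out) <- NULL
  attr(out, "removed") <- c(low = sum(low), high = sum(high))
  out
}

#' @rdname filter_range
#' @param x a [filter_range()] result.
#' @export
filter_removed <- function(x) attr(x, "removed")

# squared distance from points (px, py) to one segment (x0,y0)-(x1,y1)
.pt_seg_dist2 <- function(px, py, x0, y0, x1, y1) {
  dx <- x1 - x0
  dy <- y1 - y0
  len2 <- dx * dx + dy * dy
  t <- if (len2 > 0) pmin(1, pmax(0, ((px - x0) * dx + (py - y0) * dy) / len2)) else 0
  (px - (x0 + t * dx))^2 + (py - (y0 + t * dy))^2
}

#' Assign points to their nearest street segment
#'
#' Each point is assigned to the segment whose polyline (perpendicular foot
#' or nearest endpoint) is closest; points farther than `max_dist` from
#' every segment are left unassigned (`NA`). Exact distance ties are broken
#' by the smaller `segment_id`, so assignment is deterministic. A uniform
#' grid index over segment bounding boxes keeps the search local, so large
#' campaigns snap in roughly linear time.
#'
#' @param points data.frame with columns `x`, `y` (planar metres).
#' @param network a `street_network`.
#' @param max_dist maximum assignment distance in metres (default 50).
#' @return integer vector of `segment_id` (NA when unassigned), with the
#'   matched distances in attribute `"distance"`.
#' @export
snap_to_segment <- function(points, network, max_dist = 50) {
  if (!inherits(network, "street_network") || nrow(network$segments) == 0)
    stop("`network` must be a non-empty street_network")
  if (!is.finite(max_dist) || max_dist <= 0)
    stop("`max_dist` must be > 0")
  s <- network$segments
  n_pt <- nrow(points)
  if (n_pt == 0)
    return(structure(integer(0), distance = numeric(0)))

  cell <- max(max_dist, network$spacing %||% 50)
  x0 <- min(s$x0, s$x1, points$x) - cell
  y0 <- min(s$y0, s$y1, points$y) - cell
  cx <- function(x) as.integer(floor((x - x0) / cell))
  cy <- function(y) as.integer(floor((y - y0) / cell))

  # register each segment in every cell its bbox (padded by max_dist) touches
  sx0 <- cx(pmin(s$x0, s$x1) - max_dist); sx1 <- cx(pmax(s$x0, s$x1) + max_dist)
  sy0 <- cy(pmin(s$y0, s$y1) - max_dist); sy1 <- cy(pmax(s$y0, s$y1) + max_dist)
  reps <- (sx1 - sx0 + 1L) * (sy1 - sy0 + 1L)
  seg_idx <- rep.int(seq_len(nrow(s)), reps)
  gx <- unlist(lapply(seq_len(nrow(s)), function(i) rep(sx0[i]:sx1[i],
                times = sy1[i] - sy0[i] + 1L)), use.names = FALSE)
  gy <- unlist(lapply(seq_len(nrow(s)), function(i) rep(sy0[i]:sy1[i],
                each = sx1[i] - sx0[i] + 1L)), use.names = FALSE)
  seg_by_cell <- split(seg_idx, paste(gx, gy))

  pt_key <- paste(cx(points$x), cy(points$y))
  ans <- rep(NA_integer_, n_pt)
  dist <- rep(NA_real_, n_pt)
  max2 <- max_dist^2
  for (key in unique(pt_key)) {
    cand <- seg_by_cell[[key]]
    if (is.null(cand)) next
    pts <- which(pt_key == key)
    best_d2 <- rep(Inf, length(pts))
    best_id <- rep(NA_integer_, length(pts))
    for (j in cand) {
      d2 <- .pt_seg_dist2(points$x[pts], points$y[pts],
                          s$x0[j], s$y0[j], s$x1[j], s$y1[j])
      id <- s$segment_id[j]
      take <- d2 < best_d2 | (d2 == best_d2 & id < best_id)
      take[is.na(take)] <- FALSE
      best_d2[take] <- d2[take]
      best_id[take] <- id
    }
    ok <- best_d2 <= max2
    ans[pts[ok]] <- best_id[ok]
    dist[pts[ok]] <- sqrt(best_d2[ok])
  }
  structure(ans, distance = dist)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Aggregate 1 Hz records to drive-pass means
#'
#' A drive-pass is all records on one street segment during one calendar
#' day. Each pass is summarised by the arithmetic mean of its records and
#' the number of contributing seconds.
#'
#' @param records data.frame with `segment_id`, `timestamp` (POSIXct) and a
#'   concentration column `no2_ugm3`; records with `NA` segment (unsnapped)
#'   are dropped.
#' @return data.frame of `SegmentPassMean`s: `segment_id`, `pass_date`
#'   (Date), `mean_conc`, `n_seconds`, one row per (segment, day), ordered
#'   by segment then date.
#' @export
aggregate_passes <- function(records) {
  dt <- data.table::as.data.table(records)[!is.na(segment_id)]
  dt[, pass_date := as.Date(timestamp, tz = "UTC")]
  out <- dt[, .(mean_conc = mean(no2_ugm3), n_seconds = .N),
            by = .(segment_id, pass_date)]
  data.table::setorder(out, segment_id, pass_date)
  data.table::setDF(out)
  out
}

#' Summarise drive-pass means into the data-only map
#'
#' Per segment: the unweighted mean of its drive-pass means (the "mean of
#' means" -- pass durations are deliberately ignored so long passes do not
#' dominate), the pass count, and the standard error of the mean (sample SD
#' of pass means over the square root of the pass count; `NA` for
#' single-pass segments, where between-pass spread is unobservable).
#'
#' @param pass_means output of [aggregate_passes()].
#' @return data.frame of `SegmentSummary`s: `segment_id`, `mean_of_means`,
#'   `n_passes`, `sem`.
#' @export
summarize_segments <- function(pass_means) {
  dt <- data.table::as.data.table(pass_means)
  out <- dt[, .(mean_of_means = mean(mean_conc),
                n_passes = .N,
                sem = if (.N >= 2L) sd(mean_conc) / sqrt(.N) else NA_real_),
            by = segment_id]
  data.table::setorder(out, segment_id)
  data.table::setDF(out)
  out
}
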