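#' Read and write campaign files
#'
#' Plain-text interchange formats: measurements and reference series as CSV
#' with ISO-8601 UTC timestamps, street networks as GeoJSON
#' FeatureCollections of LineStrings whose properties carry the segment id
#' and covariates (expected coefficient signs ride along in the top-level
#' `expected_sign` member), and map layers as CSV.
#'
#' @param records data.frame with a `timestamp` column (POSIXct).
#' @param path file path.
#' @name segmap-io
NULL

#' @rdname segmap-io
#' @export
write_measurements_csv <- function(records, path) {
  out <- records
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname segmap-io
#' @export
read_measurements_csv <- function(path) {
  x <- data.table::fread(path, data.table = FALSE)
  x$timestamp <- as.POSIXct(x$timestamp, tz = "UTC",
                            format = "%Y-%m-%dT%H:%M:%OSZ")
  x
}

#' @rdname segmap-io
#' @param network a `street_network`.
#' @export
write_network_geojson <- function(network, path) {
  s <- network$segments
  cov <- network$covariates
  features <- lapply(seq_len(nrow(s)), function(i) {
    props <- c(list(segment_id = s$segment_id[i], length = s$length[i]),
               as.list(cov[i, setdiff(names(cov), "segment_id")]))
    list(
      type = "Feature",
      geometry = list(
        type = "LineString",
        coordinates = list(c(s$x0[i], s$y0[i]), c(s$x1[i], s$y1[i]))
      ),
      properties = props
    )
  })
  obj <- list(type = "FeatureCollection",
              expected_sign = as.list(network$expected_sign),
              features = features)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname segmap-io
#' @export
read_network_geojson <- function(path) {
  obj <- jsonlite::read_json(path)
  if (!identical(obj$type, "FeatureCollection"))
    stop("not a GeoJSON FeatureCollection: ", path)
  feats <- obj$features
  coords <- lapply(feats, function(f) f$geometry$coordinates)
  props <- lapply(feats, function(f) f$properties)
  segs <- data.frame(
    segment_id = vapply(props, function(p) as.integer(p$segment_id), 1L),
    x0 = vapply(coords, function(cc) as.numeric(cc[[1]][[1]]), 1),
    y0 = vapply(coords, function(cc) as.numeric(cc[[1]][[2]]), 1),
    x1 = vapply(coords, function(cc) as.numeric(cc[[2]][[1]]), 1),
    y1 = vapply(coords, function(cc) as.numeric(cc[[2]][[2]]), 1)
  )
  segs$xm <- (segs$x0 + segs$x1) / 2
  segs$ym <- (segs$y0 + segs$y1) / 2
  segs$length <- sqrt((segs$x1 - segs$x0)^2 + (segs$y1 - segs$y0)^2)
  covnames <- setdiff(names(props[[1]]), c("segment_id", "length"))
  cov <- data.frame(segment_id = segs$segment_id)
  for (nm in covnames)
    cov[[nm]] <- vapply(props, function(p) as.numeric(p[[nm]]), 1)
  structure(
    list(segments = segs, covariates = cov,
         expected_sign = unlist(obj$expected_sign),
         spacing = stats::median(segs$length)),
    class = "street_network"
  )
}

#' @rdname segmap-io
#' @param fit a `lur_fit`.
#' @export
write_lur_report <- function(fit, path) {
  jsonlite::write_json(
    list(selected = fit$selected,
         coefficients = as.list(fit$coefficients),
         r2 = fit$r2, adj_r2 = fit$adj_r2,
         p_values = as.list(fit$p_values),
         n = fit$n),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
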