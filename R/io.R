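#' Write / read a signal as CSV plus JSON sidecar
#'
#' The record itself goes to a two-column CSV (`time_s`, `current`); the
#' protocol, boundary annotations and any anomaly descriptor go to a JSON
#' sidecar (`<path>.json`), so the pair round-trips an `apta_signal`.
#'
#' @param signal an `apta_signal`.
#' @param path CSV file path.
#' @return `write_signal_csv()` returns `path` invisibly;
#'   `read_signal_csv()` returns the reconstructed `apta_signal`.
#' @export
write_signal_csv <- function(signal, path) {
  check_signal(signal)
  utils::write.csv(as.data.frame(signal[, c("time_s", "current")]),
                   path, row.names = FALSE)
  proto <- signal_protocol(signal)
  anom <- signal_anomaly(signal)
  meta <- list(
    protocol = unclass(proto),
    boundaries = as.data.frame(signal_boundaries(signal)),
    anomaly = if (!is.null(anom)) unclass(anom),
    normalized = isTRUE(attr(signal, "normalized")),
    mu = attr(signal, "mu"), sigma = attr(signal, "sigma")
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_signal_csv
#' @export
read_signal_csv <- function(path) {
  d <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  proto <- NULL
  if (!is.null(meta$protocol)) {
    proto <- structure(meta$protocol, class = "sensing_protocol")
    proto$samples_per_segment <- as.integer(proto$samples_per_segment)
  }
  anom <- if (!is.null(meta$anomaly)) structure(meta$anomaly, class = "anomaly_spec")
  b <- tibble::as_tibble(meta$boundaries)
  b$start <- as.integer(b$start); b$end <- as.integer(b$end)
  new_apta_signal(d$time_s, d$current, proto, b, anomaly = anom,
                  normalized = isTRUE(meta$normalized),
                  mu = meta$mu %||% NA_real_, sigma = meta$sigma %||% NA_real_)
}

#' Write / read a segment table
#'
#' Long-format CSV (`segment_id`, `sample`, `value`) plus a JSON sidecar
#' holding the per-segment metadata.
#'
#' @param segments an `apta_segments` tibble.
#' @param path CSV file path.
#' @return `write_segments_csv()` returns `path` invisibly;
#'   `read_segments_csv()` the reconstructed table.
#' @export
write_segments_csv <- function(segments, path) {
  long <- tidyr::unnest_longer(
    dplyr::select(segments, "segment_id", "values"),
    "values", values_to = "value", indices_to = "sample"
  )
  utils::write.csv(as.data.frame(long[, c("segment_id", "sample", "value")]),
                   path, row.names = FALSE)
  meta <- dplyr::select(segments, -"values")
  jsonlite::write_json(as.data.frame(meta), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_segments_csv
#' @export
read_segments_csv <- function(path) {
  long <- utils::read.csv(path)
  meta <- tibble::as_tibble(jsonlite::read_json(paste0(path, ".json"),
                                                simplifyVector = TRUE))
  vals <- split(long$value, factor(long$segment_id, levels = meta$segment_id))
  meta$values <- lapply(meta$segment_id, function(id) as.numeric(vals[[id]]))
  meta$n <- lengths(meta$values)
  class(meta) <- c("apta_segments", class(meta))
  meta
}
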