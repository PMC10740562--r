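#' Z-score normalize a whole record
#'
#' Normalization is applied to the entire record before segmentation:
#' every sample becomes `(x - mu) / sigma` with `mu` and `sigma` computed
#' from the whole signal. The population standard deviation (divide by N)
#' is used; downstream use is scale-free so the choice is immaterial, but
#' it is fixed here for reproducibility. The original `mu` and `sigma` are
#' recorded on the returned object.
#'
#' @param signal an `apta_signal`.
#' @return the normalized `apta_signal` (attributes `normalized = TRUE`,
#'   `mu`, `sigma` set).
#' @examples
#' s <- generate_signal(sensing_protocol("adenosine35"), kinetics_params())
#' z <- zscore_normalize(s)
#' c(mean(z$current), sd(z$current))
#' @export
zscore_normalize <- function(signal) {
  check_signal(signal)
  x <- signal$current
  if (length(x) < 2) abort("signal must contain at least two samples.")
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))
  if (sigma <= 0 || !is.finite(sigma)) {
    abort("signal has zero variance; z-score normalization is undefined.")
  }
  out <- signal
  out$current <- (x - mu) / sigma
  sr <- attr(signal, "step_response")
  if (!is.null(sr)) attr(out, "step_response") <- sr / sigma
  attr(out, "normalized") <- TRUE
  attr(out, "mu") <- mu
  attr(out, "sigma") <- sigma
  out
}

#' Split a record into its constant-concentration segments
#'
#' Cuts the record at its boundary annotations: one segment per interval,
#' values copied verbatim (no per-segment re-normalization). A segment is
#' the unit of all downstream analysis -- the portion of a record over
#' which the analyte concentration is constant.
#'
#' @param signal a (typically normalized) `apta_signal` with boundaries.
#' @param signal_id optional identifier recorded on each segment.
#' @param is_anomaly logical; marks every produced segment anomalous.
#'   Defaults to whether the signal carries an anomaly descriptor.
#' @return an `apta_segments` tibble with columns `segment_id`,
#'   `signal_id`, `dataset_id`, `concentration` (molar; 0 = no analyte),
#'   `is_anomaly`, `augmented`, `extrapolated`, `n` and a `values`
#'   list-column.
#' @export
segmentize <- function(signal, signal_id = "signal", is_anomaly = NULL) {
  check_signal(signal)
  b <- signal_boundaries(signal)
  b <- b[order(b$start), ]
  if (any(b$end[-nrow(b)] > b$start[-1])) abort("overlapping boundaries.")
  is_anomaly <- is_anomaly %||% !is.null(signal_anomaly(signal))
  proto <- signal_protocol(signal)
  vals <- lapply(seq_len(nrow(b)), function(i) signal$current[(b$start[i] + 1L):b$end[i]])
  out <- tibble::tibble(
    segment_id = paste0(signal_id, "_seg", seq_len(nrow(b))),
    signal_id = signal_id,
    dataset_id = if (is.null(proto)) NA_character_ else proto$dataset_id,
    concentration = b$concentration,
    is_anomaly = is_anomaly,
    augmented = FALSE,
    extrapolated = FALSE,
    n = lengths(vals),
    values = vals
  )
  class(out) <- c("apta_segments", class(out))
  out
}

#' Segment every record of a dataset
#'
#' Convenience wrapper mapping [zscore_normalize()] then [segmentize()]
#' over the `signal` list-column of a [generate_dataset()] table.
#'
#' @param dataset a tibble as returned by [generate_dataset()].
#' @return one `apta_segments` tibble covering all records.
#' @export
segmentize_dataset <- function(dataset) {
  segs <- purrr::pmap(
    list(dataset$signal, dataset$signal_id),
    function(sig, id) segmentize(zscore_normalize(sig), signal_id = id)
  )
  out <- dplyr::bind_rows(segs)
  class(out) <- c("apta_segments", class(out))
  out
}

#' Resample a segment to a fixed length
#'
#' Linear interpolation onto a uniform grid spanning the segment's own
#' range; endpoints are preserved exactly and affine signals stay affine.
#' Used to bring 166-sample oestradiol segments to the 300-sample working
#' length.
#'
#' @param segment a numeric vector, or an `apta_segments` tibble (all rows
#'   are resampled).
#' @param target_length requested output length (default 300).
#' @return same shape as the input with each segment of length
#'   `target_length`.
#' @examples
#' length(resample_segment(sin(seq_len(166) / 10), 300))
#' @export
resample_segment <- function(segment, target_length = 300L) {
  if (target_length < 2) abort("`target_length` must be at least 2.")
  if (is.numeric(segment)) {
    n <- length(segment)
    if (n < 2) abort("segment must contain at least two samples.")
    if (n == target_length) return(segment)
    return(approx(seq(0, 1, length.out = n), segment,
                  xout = seq(0, 1, length.out = target_length))$y)
  }
  out <- segment
  out$values <- lapply(out$values, resample_segment, target_length = target_length)
  out$n <- lengths(out$values)
  out
}

#' Standardize segment lengths across a table
#'
#' Downstream models require a uniform segment length (166, 300 or 500
#' samples). Over-long segments -- e.g. the analyte-free baseline, which
#' lasts longer than one injection step -- are trimmed to their trailing
#' `target_length` samples (the part closest to steady state); shorter
#' segments are linearly resampled up with [resample_segment()].
#'
#' @param segments an `apta_segments` tibble.
#' @param target_length working length in samples.
#' @return the table with every `values` entry of length `target_length`.
#' @export
standardize_segments <- function(segments, target_length) {
  segments$values <- lapply(segments$values, function(v) {
    if (length(v) > target_length) {
      v[(length(v) - target_length + 1L):length(v)]
    } else if (length(v) < target_length) {
      resample_segment(v, target_length)
    } else v
  })
  segments$n <- lengths(segments$values)
  segments
}

# class index <-> concentration maps (No Analyte = 0 M)
conc_ladder_full <- c(0, 1e-9, 1e-8, 1e-7, 1e-6, 1e-5)

conc_index <- function(concentration) {
  idx <- vapply(concentration, function(cc) {
    hit <- which(abs(log10(pmax(conc_ladder_full, 1e-30)) -
                       log10(max(cc, 1e-30))) < 1e-6)
    if (length(hit) != 1) NA_integer_ else as.integer(hit)
  }, integer(1))
  if (anyNA(idx)) abort("concentration outside the No Analyte .. 10 uM ladder.")
  idx
}

#' Assign class labels under the C1 or C2 scheme
#'
#' Two labeling schemes are used. C1 is the per-dataset six-class task:
#' No Analyte = 1 up to 10 uM = 6, identical for every dataset, normal
#' segments only. C2 is the cross-dataset twelve-class task: the adenosine
#' dataset keeps classes 1-6, the oestradiol datasets share No Analyte = 1
#' but map 1 nM .. 10 uM to classes 7-11, and every anomalous segment --
#' whatever its dataset -- is class 12.
#'
#' @param segments an `apta_segments` tibble (or a one-row slice).
#' @param scheme `"C1"` or `"C2"`.
#' @return an integer vector of labels, one per row.
#' @examples
#' segs <- tibble::tibble(dataset_id = "oestradiol31", concentration = 1e-9,
#'                        is_anomaly = FALSE)
#' assign_labels(segs, "C2")  # 7
#' @export
assign_labels <- function(segments, scheme = c("C1", "C2")) {
  scheme <- match.arg(scheme)
  anom <- segments$is_anomaly
  if (scheme == "C1") {
    if (any(anom)) abort("anomalous segments carry no C1 label.")
    return(conc_index(segments$concentration))
  }
  out <- integer(nrow(segments))
  out[anom] <- 12L
  if (any(!anom)) {
    ci <- conc_index(segments$concentration[!anom])
    oest <- grepl("^oestradiol", segments$dataset_id[!anom])
    lab <- ci
    lab[oest & ci > 1L] <- ci[oest & ci > 1L] + 5L
    out[!anom] <- lab
  }
  out
}

#' Blackman window
#'
#' Periodic Blackman taper `w[n] = a0 - a1 cos(2 pi n / N) + a2 cos(4 pi n
#' / N)` for `n = 0 .. N-1`, with `a0 = (1 - alpha)/2`, `a1 = 1/2`,
#' `a2 = alpha/2`. With the classical `alpha = 0.16` the endpoint weight is
#' exactly 0 and the peak weight 1.
#'
#' @param N window length in samples.
#' @param alpha shape parameter (default 0.16).
#' @return numeric vector of `N` weights in `[0, 1]`.
#' @export
blackman_window <- function(N, alpha = 0.16) {
  if (N < 2) abort("`N` must be at least 2.")
  n <- seq_len(N) - 1
  a0 <- (1 - alpha) / 2
  a1 <- 1 / 2
  a2 <- alpha / 2
  a0 - a1 * cos(2 * pi * n / N) + a2 * cos(4 * pi * n / N)
}

#' STFT configuration
#'
#' Defaults reproduce the working setup: 128-sample Blackman window, 64
#' samples of overlap between adjoining frames, 128-point transform.
#'
#' @param window_length analysis window length, samples.
#' @param overlap overlap between adjoining frames, samples.
#' @param fft_length transform length, points (`>= window_length`).
#' @param window_alpha Blackman shape parameter.
#' @param db logical; if `TRUE` the spectrogram is reported in decibels
#'   (`10 log10`) instead of the default linear squared magnitude.
#' @return an object of class `stft_config`.
#' @export
stft_config <- function(window_length = 128L, overlap = 64L,
                        fft_length = 128L, window_alpha = 0.16,
                        db = FALSE) {
  if (!(overlap >= 0 && overlap < window_length && window_length <= fft_length)) {
    abort("need 0 <= overlap < window_length <= fft_length.")
  }
  structure(list(window_length = as.integer(window_length),
                 overlap = as.integer(overlap),
                 fft_length = as.integer(fft_length),
                 window_alpha = window_alpha, db = db),
            class = "stft_config")
}

#' Spectrogram of a segment
#'
#' Short-time Fourier transform with a Blackman window: frames of
#' `window_length` samples are taken at hop `window_length - overlap`, with
#' no tail padding (frames that would overrun the segment end are dropped),
#' windowed, transformed with `fft_length` points, and squared in
#' magnitude. All `fft_length` frequency rows of the two-sided transform
#' are retained, so a 300-sample segment yields a 128 x 3 matrix and a
#' 500-sample segment a 128 x 6 matrix under the defaults.
#'
#' @param segment numeric vector (one segment's samples).
#' @param config an [stft_config()].
#' @return an `apta_spectrogram`: a nonnegative `fft_length x n_frames`
#'   matrix with attribute `frame_hop`.
#' @examples
#' dim(compute_spectrogram(rnorm(300), stft_config()))  # 128 3
#' @export
compute_spectrogram <- function(segment, config = stft_config()) {
  stopifnot(is.numeric(segment))
  wl <- config$window_length
  if (length(segment) < wl) abort("segment shorter than the analysis window.")
  hop <- wl - config$overlap
  n_frames <- 1L + (length(segment) - wl) %/% hop
  w <- blackman_window(wl, config$window_alpha)
  S <- matrix(0, nrow = config$fft_length, ncol = n_frames)
  for (f in seq_len(n_frames)) {
    fr <- segment[((f - 1L) * hop + 1L):((f - 1L) * hop + wl)] * w
    if (config$fft_length > wl) fr <- c(fr, numeric(config$fft_length - wl))
    S[, f] <- Mod(fft(fr))^2
  }
  if (config$db) S <- 10 * log10(pmax(S, .Machine$double.xmin))
  structure(S, class = "apta_spectrogram", frame_hop = hop)
}

#' Attach spectrograms to a segment table
#'
#' @param segments an `apta_segments` tibble.
#' @param config an [stft_config()].
#' @return the table with an added `spectrogram` list-column.
#' @export
add_spectrograms <- function(segments, config = stft_config()) {
  segments$spectrogram <- lapply(segments$values, compute_spectrogram, config = config)
  segments
}
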