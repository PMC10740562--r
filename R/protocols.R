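#' Sensing protocol descriptors
#'
#' A sensing protocol describes how one aptasensor experiment is run: the
#' sampling interval of the drain-current readout, the duration of the
#' initial analyte-free baseline, the duration of each injection step, and
#' the ladder of analyte concentrations injected in increasing order.
#' Defaults follow the published procedures for the three sensor families:
#' the 35-mer adenosine sensor (1 s sampling, 1000 s baseline, 500 s steps)
#' and the 31-/35-mer oestradiol sensors (1.081 s sampling, 600 s baseline,
#' 300 s injection steps, ladder 1 nM to 10 uM).
#'
#' `samples_per_segment` fixes the number of samples each injection step
#' contributes. For the adenosine protocol this equals
#' `step_duration / sampling_interval` (500); for the oestradiol protocols
#' the conventional per-segment count of 166 samples is used even though the
#' duration arithmetic would suggest ~277 -- the per-segment count is taken
#' as authoritative so that the 166-to-300 resampling path is exercised.
#'
#' @param dataset_id one of `"adenosine35"`, `"oestradiol31"`,
#'   `"oestradiol35"`.
#' @param sampling_interval sampling interval in seconds.
#' @param baseline_duration duration of the analyte-free baseline, seconds.
#' @param step_duration duration of each injection step, seconds.
#' @param concentration_ladder strictly increasing molar concentrations.
#' @param samples_per_segment samples contributed by each injection step.
#' @return an object of class `sensing_protocol` (a named list).
#' @examples
#' sensing_protocol("adenosine35")
#' sensing_protocol("oestradiol31")$samples_per_segment  # 166
#' @export
sensing_protocol <- function(dataset_id = c("adenosine35", "oestradiol31", "oestradiol35"),
                             sampling_interval = NULL,
                             baseline_duration = NULL,
                             step_duration = NULL,
                             concentration_ladder = NULL,
                             samples_per_segment = NULL) {
  dataset_id <- match.arg(dataset_id)
  adeno <- dataset_id == "adenosine35"
  p <- list(
    dataset_id = dataset_id,
    sampling_interval = sampling_interval %||% if (adeno) 1.0 else 1.081,
    baseline_duration = baseline_duration %||% if (adeno) 1000 else 600,
    step_duration = step_duration %||% if (adeno) 500 else 300,
    concentration_ladder = concentration_ladder %||% c(1e-9, 1e-8, 1e-7, 1e-6, 1e-5),
    samples_per_segment = samples_per_segment %||% if (adeno) 500L else 166L
  )
  p$samples_per_segment <- as.integer(p$samples_per_segment)
  validate_protocol(p)
  structure(p, class = "sensing_protocol")
}

validate_protocol <- function(p) {
  if (p$sampling_interval <= 0) abort("`sampling_interval` must be positive.")
  if (p$step_duration <= 0 || p$baseline_duration <= 0) {
    abort("`baseline_duration` and `step_duration` must be positive.")
  }
  if (length(p$concentration_ladder) == 0) abort("`concentration_ladder` must not be empty.")
  if (any(p$concentration_ladder <= 0)) abort("concentrations must be positive (molar).")
  if (is.unsorted(p$concentration_ladder, strictly = TRUE)) {
    abort("`concentration_ladder` must be strictly increasing.")
  }
  if (p$samples_per_segment < 2) abort("`samples_per_segment` must be at least 2.")
  invisible(p)
}

#' Response-kinetics parameters for the signal generator
#'
#' The deterministic part of a simulated drain-current record is a staircase:
#' each injection step approaches a new plateau with first-order kinetics
#' (`1 - exp(-u / response_time_constant)` in the time `u` since injection),
#' the plateau offset above baseline growing by `step_gain` per decade of
#' analyte concentration. On top of the staircase sit a linear drift, white
#' Gaussian readout noise and a short exponential injection spike.
#'
#' @param baseline_level baseline drain current, arbitrary units (a.u.).
#' @param step_gain plateau amplitude scale, a.u.; with the default
#'   `dose_exponent` the full ladder spans `step_gain * 5^0.5`, so the
#'   default 1.118 puts the top-of-ladder response at 2.5 a.u. --
#'   a 25% modulation of the 10 a.u. baseline current.
#' @param dose_exponent saturation exponent of the dose response: the
#'   plateau offset for the j-th decade above the lowest ladder
#'   concentration is `step_gain * j^dose_exponent`. Values below 1 give
#'   the sub-linear growth of a saturating binding isotherm at high
#'   analyte concentration; the default 0.5 keeps whole-record z-scores
#'   within the conventional normal-data range of about [-1.5, 1.5].
#' @param response_time_constant first-order response time constant,
#'   seconds; the slow approach of the drain current to its new plateau
#'   after an injection (binding equilibration).
#' @param drift_slope linear drift, a.u. per second.
#' @param noise_sd standard deviation of the readout noise, a.u.
#' @param spike_amplitude amplitude of the injection artifact, a.u.
#' @param seed integer seed making the generated record reproducible.
#' @return an object of class `kinetics_params`.
#' @export
kinetics_params <- function(baseline_level = 10,
                            step_gain = 1.118,
                            dose_exponent = 0.5,
                            response_time_constant = 120,
                            drift_slope = 0,
                            noise_sd = 0.05,
                            spike_amplitude = 0,
                            seed = 1L) {
  if (response_time_constant <= 0) abort("`response_time_constant` must be positive.")
  if (noise_sd < 0) abort("`noise_sd` must be nonnegative.")
  if (dose_exponent <= 0) abort("`dose_exponent` must be positive.")
  structure(list(
    baseline_level = baseline_level, step_gain = step_gain,
    dose_exponent = dose_exponent,
    response_time_constant = response_time_constant,
    drift_slope = drift_slope, noise_sd = noise_sd,
    spike_amplitude = spike_amplitude, seed = as.integer(seed)
  ), class = "kinetics_params")
}

#' Anomaly descriptors
#'
#' Three anomaly archetypes are supported, mirroring the failure modes seen
#' in real recordings: `non_sensing` (the sensor fails to respond to
#' injections, so step responses are suppressed), `broken_transistor`
#' (large erratic excursions across the whole record) and
#' `abnormal_interval` (a disturbance confined to a stated time interval).
#'
#' `magnitude` scales the perturbation; `magnitude = 0` leaves the signal
#' untouched for every kind. For `non_sensing` the magnitude (clamped to
#' `[0, 1]`) is the fraction of the step response removed. The
#' `broken_transistor` default of 1.8 a.u. is calibrated so that, under the
#' default kinetics, z-scored faulty records span roughly `[-5, 5]`.
#'
#' @param kind `"non_sensing"`, `"broken_transistor"` or `"abnormal_interval"`.
#' @param interval numeric `c(start_s, end_s)`; used only for
#'   `abnormal_interval`.
#' @param magnitude nonnegative perturbation scale, a.u.
#' @return an object of class `anomaly_spec`.
#' @export
anomaly_spec <- function(kind = c("non_sensing", "broken_transistor", "abnormal_interval"),
                         interval = NULL,
                         magnitude = NULL) {
  kind <- match.arg(kind)
  magnitude <- magnitude %||% switch(kind,
    non_sensing = 1, broken_transistor = 1.8, abnormal_interval = 1
  )
  if (magnitude < 0) abort("`magnitude` must be nonnegative.")
  if (kind == "abnormal_interval") {
    if (is.null(interval) || length(interval) != 2 || interval[1] >= interval[2]) {
      abort("`abnormal_interval` requires `interval = c(start_s, end_s)` with start < end.")
    }
  }
  structure(list(kind = kind, interval = interval, magnitude = magnitude),
            class = "anomaly_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
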