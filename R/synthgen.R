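#' Simulate one aptasensor drain-current record
#'
#' Builds a full drain-current record for one experiment: an analyte-free
#' baseline of `baseline_duration` seconds followed by one injection step
#' per entry of the concentration ladder. Within each step the current
#' approaches its new plateau with first-order kinetics; the plateau offset
#' above baseline is `step_gain * d^dose_exponent` with `d` the number of
#' decades above the lowest ladder concentration (plus one), so plateau
#' levels grow monotonically -- but saturating -- with the logarithm of
#' concentration. Linear drift, Gaussian readout noise and an optional
#' injection spike are added.
#' The record is deterministic given `kinetics$seed`.
#'
#' @param protocol a [sensing_protocol()].
#' @param kinetics a [kinetics_params()].
#' @return An object of class `apta_signal`: a tibble with columns `time_s`
#'   and `current`, carrying attributes `protocol`, `boundaries` (a tibble
#'   of 0-based half-open index intervals with their concentration labels),
#'   `kinetics`, `anomaly` (or `NULL`) and `step_response` (the noiseless
#'   staircase component, kept so anomalies can suppress it exactly).
#' @examples
#' sig <- generate_signal(
#'   sensing_protocol("adenosine35", concentration_ladder = c(1e-6, 1e-5)),
#'   kinetics_params(seed = 7)
#' )
#' signal_boundaries(sig)
#' @export
generate_signal <- function(protocol, kinetics) {
  validate_protocol(protocol)
  stopifnot(inherits(kinetics, "kinetics_params"))
  dt <- protocol$sampling_interval
  n_base <- as.integer(round(protocol$baseline_duration / dt))
  sps <- protocol$samples_per_segment
  ladder <- protocol$concentration_ladder
  n_steps <- length(ladder)
  n <- n_base + n_steps * sps
  t <- (seq_len(n) - 1) * dt

  # plateau amplitudes: saturating growth in decades above the lowest
  # ladder concentration (see ?kinetics_params)
  decades <- log10(ladder) - log10(ladder[1]) + 1
  amp <- kinetics$step_gain * decades^(kinetics$dose_exponent %||% 1)
  step_resp <- numeric(n)
  spike <- numeric(n)
  prev <- 0
  for (j in seq_len(n_steps)) {
    i0 <- n_base + (j - 1L) * sps
    idx <- (i0 + 1L):(i0 + sps)
    u <- (seq_len(sps) - 1) * dt
    step_resp[idx] <- prev + (amp[j] - prev) * (1 - exp(-u / kinetics$response_time_constant))
    if (kinetics$spike_amplitude != 0) {
      spike[idx] <- kinetics$spike_amplitude * exp(-u / (2 * dt))
    }
    prev <- amp[j]
  }
  set.seed(kinetics$seed)
  noise <- rnorm(n, 0, kinetics$noise_sd)
  values <- kinetics$baseline_level + kinetics$drift_slope * t + step_resp + spike + noise

  boundaries <- tibble::tibble(
    start = c(0L, n_base + (seq_len(n_steps) - 1L) * sps),
    end = c(n_base, n_base + seq_len(n_steps) * sps),
    concentration = c(0, ladder)
  )
  new_apta_signal(t, values, protocol, boundaries,
                 kinetics = kinetics, step_response = step_resp)
}

new_apta_signal <- function(time_s, current, protocol, boundaries,
                            kinetics = NULL, step_response = NULL,
                            anomaly = NULL, normalized = FALSE,
                            mu = NA_real_, sigma = NA_real_) {
  x <- tibble::tibble(time_s = time_s, current = current)
  structure(x,
    class = c("apta_signal", class(x)),
    protocol = protocol, boundaries = boundaries, kinetics = kinetics,
    step_response = step_response, anomaly = anomaly,
    normalized = normalized, mu = mu, sigma = sigma
  )
}

#' Accessors for `apta_signal` metadata
#'
#' @param signal an `apta_signal`.
#' @return `signal_boundaries()` returns the tibble of 0-based half-open
#'   boundary intervals; `signal_protocol()` the [sensing_protocol()];
#'   `signal_anomaly()` the [anomaly_spec()] or `NULL`.
#' @export
signal_boundaries <- function(signal) attr(signal, "boundaries")

#' @rdname signal_boundaries
#' @export
signal_protocol <- function(signal) attr(signal, "protocol")

#' @rdname signal_boundaries
#' @export
signal_anomaly <- function(signal) attr(signal, "anomaly")

check_signal <- function(signal) {
  if (!inherits(signal, "apta_signal")) abort("expected an `apta_signal`.")
  b <- signal_boundaries(signal)
  if (is.null(b) || nrow(b) == 0) abort("signal has no boundary annotations.")
  ord <- order(b$start)
  if (any(b$end[ord][-nrow(b)] != b$start[ord][-1]) ||
      b$start[ord][1] != 0L || b$end[ord][nrow(b)] != nrow(signal)) {
    abort("boundaries must tile the signal without gaps or overlap.")
  }
  invisible(signal)
}

#' Inject an anomaly into a simulated record
#'
#' Applies one of the three anomaly archetypes to a record. `non_sensing`
#' subtracts (a `magnitude`-scaled fraction of) the staircase step response,
#' leaving plateau offsets near zero; `broken_transistor` adds large sparse
#' erratic excursions across the whole record; `abnormal_interval` adds an
#' oscillatory disturbance confined to `spec$interval` (seconds), leaving
#' every sample outside the interval bit-identical to the input. Boundary
#' annotations are preserved and the anomaly descriptor is recorded.
#' Stochastic perturbations draw from the current RNG stream; seed the
#' session (or use [generate_dataset()]) for reproducibility.
#'
#' @param signal an `apta_signal`.
#' @param spec an [anomaly_spec()].
#' @return the perturbed `apta_signal` with its `anomaly` attribute set.
#' @export
inject_anomaly <- function(signal, spec) {
  check_signal(signal)
  stopifnot(inherits(spec, "anomaly_spec"))
  v <- signal$current
  t <- signal$time_s
  n <- length(v)
  if (spec$kind == "non_sensing") {
    sr <- attr(signal, "step_response")
    if (is.null(sr)) abort("signal carries no step-response component to suppress.")
    v <- v - min(spec$magnitude, 1) * sr
  } else if (spec$kind == "broken_transistor") {
    burst <- rnorm(n) * (runif(n) < 0.05)
    v <- v + spec$magnitude * burst
  } else { # abnormal_interval
    if (spec$interval[1] < t[1] || spec$interval[2] > t[n]) {
      abort("anomaly `interval` lies outside the record.")
    }
    idx <- which(t >= spec$interval[1] & t <= spec$interval[2])
    u <- t[idx] - t[idx[1]]
    v[idx] <- v[idx] + spec$magnitude * (sin(2 * pi * u / 20) + 0.5)
  }
  out <- signal
  out$current <- v
  attr(out, "anomaly") <- spec
  out
}

#' Population sampler for per-signal kinetics
#'
#' Real sensors differ in gain, response speed, drift and noise from chip to
#' chip. `kinetics_population()` returns a sampler that draws per-signal
#' [kinetics_params()] around a base parameter set with multiplicative
#' jitter on the gain and time constant and additive jitter on baseline and
#' drift, emulating that between-sensor variability.
#'
#' @param base a [kinetics_params()] giving the population centre.
#' @param gain_cv coefficient of variation of `step_gain`.
#' @param tau_cv coefficient of variation of `response_time_constant`.
#' @param baseline_sd additive spread of `baseline_level`, a.u.
#' @param drift_sd spread of `drift_slope`, a.u./s.
#' @return a function `f(n)` returning a list of `n` [kinetics_params()]
#'   (seeds are filled in by the caller).
#' @export
kinetics_population <- function(base = kinetics_params(),
                                gain_cv = 0.1, tau_cv = 0.15,
                                baseline_sd = 1, drift_sd = 2e-4) {
  function(n) {
    lapply(seq_len(n), function(i) {
      kinetics_params(
        baseline_level = base$baseline_level + rnorm(1, 0, baseline_sd),
        step_gain = base$step_gain * exp(rnorm(1, 0, gain_cv)),
        dose_exponent = base$dose_exponent %||% 0.5,
        response_time_constant = base$response_time_constant * exp(rnorm(1, 0, tau_cv)),
        drift_slope = base$drift_slope + rnorm(1, 0, drift_sd),
        noise_sd = base$noise_sd,
        spike_amplitude = base$spike_amplitude,
        seed = 1L
      )
    })
  }
}

#' Generate a synthetic dataset of sensor records
#'
#' Simulates `n_normal_per_class` normal records per protocol -- each record
#' contains the full staircase, so after segmentation every concentration
#' class receives exactly `n_normal_per_class` segments -- plus `n_anomaly`
#' anomalous records per protocol cycling through the three anomaly kinds.
#' Per-signal kinetics are drawn from `population`; everything is
#' reproducible given `seed`.
#'
#' @param protocols a [sensing_protocol()] or list of them.
#' @param population a sampler from [kinetics_population()].
#' @param n_normal_per_class number of normal records per protocol.
#' @param n_anomaly number of anomalous records per protocol.
#' @param seed integer seed.
#' @return a tibble with columns `signal_id`, `dataset_id`, `anomaly_kind`
#'   (`NA` for normal records) and a `signal` list-column of `apta_signal`s.
#' @examples
#' ds <- generate_dataset(sensing_protocol("oestradiol31"),
#'                        n_normal_per_class = 2, n_anomaly = 1, seed = 1)
#' ds$dataset_id
#' @export
generate_dataset <- function(protocols,
                             population = kinetics_population(),
                             n_normal_per_class = 10,
                             n_anomaly = 0,
                             seed = 1L) {
  if (inherits(protocols, "sensing_protocol")) protocols <- list(protocols)
  if (n_normal_per_class < 0 || n_anomaly < 0) abort("counts must be nonnegative.")
  set.seed(seed)
  kinds <- c("non_sensing", "broken_transistor", "abnormal_interval")
  rows <- list()
  for (p in protocols) {
    n_tot <- n_normal_per_class + n_anomaly
    if (n_tot == 0) next
    kin <- population(n_tot)
    seeds <- sample.int(.Machine$integer.max, n_tot)
    for (i in seq_len(n_tot)) {
      kin[[i]]$seed <- seeds[i]
      sig <- generate_signal(p, kin[[i]])
      kind <- NA_character_
      if (i > n_normal_per_class) {
        kind <- kinds[((i - n_normal_per_class - 1L) %% 3L) + 1L]
        spec <- if (kind == "abnormal_interval") {
          dur <- max(sig$time_s)
          anomaly_spec(kind, interval = c(0.3, 0.6) * dur)
        } else {
          anomaly_spec(kind)
        }
        sig <- inject_anomaly(sig, spec)
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        signal_id = paste0(p$dataset_id, "_", sprintf("%03d", i)),
        dataset_id = p$dataset_id,
        anomaly_kind = kind,
        signal = list(sig)
      )
    }
  }
  dplyr::bind_rows(rows)
}
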