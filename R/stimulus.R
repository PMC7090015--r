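## Smooth electrical Gaussian white-noise stimulus synthesis.
##
## The stimulus is delivered through capacitive electrodes, where the injected
## current is proportional to the time derivative of the electrode voltage
## (i = c dV/dt). The voltage command is therefore the running integral of the
## desired current: a reflected Gaussian random walk, low-pass filtered and
## rescaled into the safe command range. The current-proportional stimulus
## trace used for model fitting is the first difference of that command,
## standardized to zero mean and unit variance.

#' Stimulus generation settings
#'
#' @param sampling_rate Hz (default 10000).
#' @param duration total stimulus duration in seconds (default 5).
#' @param reflect_limit reflection limit of the random walk in arbitrary
#'   units (default 10). Whenever a step would push the cumulative sum beyond
#'   this bound, the step's sign is inverted.
#' @param cutoff low-pass cutoff in Hz (default 100).
#' @param filter_order Butterworth order (default 5).
#' @param voltage_range two-element numeric: safe command limits in volts
#'   (default `c(0, 2.5)`).
#' @param capacitance_scale proportionality constant between dV/dt and the
#'   stimulation current; treated as a unit constant.
#' @param seed integer seed for the Gaussian steps.
#' @return list of class `stimulus_config`.
#' @export
stimulus_config <- function(sampling_rate = 10000, duration = 5,
                            reflect_limit = 10, cutoff = 100,
                            filter_order = 5, voltage_range = c(0, 2.5),
                            capacitance_scale = 1, seed = 1L) {
  if (duration <= 0) stop("duration must be positive")
  if (reflect_limit <= 0) stop("reflect_limit must be positive")
  if (sampling_rate <= 2 * cutoff) stop("sampling_rate must exceed twice the cutoff")
  if (length(voltage_range) != 2 || diff(voltage_range) <= 0)
    stop("voltage_range must be an increasing pair")
  structure(list(sampling_rate = sampling_rate, duration = duration,
                 reflect_limit = reflect_limit, cutoff = cutoff,
                 filter_order = filter_order, voltage_range = voltage_range,
                 capacitance_scale = capacitance_scale, seed = seed),
            class = "stimulus_config")
}

#' Reflected Gaussian random walk
#'
#' Cumulative sum of standard-normal steps with a reflection rule: any step
#' whose addition would push the absolute value of the walk beyond
#' `reflect_limit` is sign-inverted before adding. In the (theoretically
#' impossible for a start inside the limits) case that the inverted step also
#' violates the bound, the walk is clamped to the limit.
#'
#' @param n_samples number of steps (>= 1).
#' @param reflect_limit positive bound on |walk|.
#' @param seed integer seed used to draw the steps (ignored when `steps`
#'   given).
#' @param steps optional explicit step vector (for deterministic
#'   construction); overrides `seed`.
#' @return numeric vector of length `n_samples`.
#' @export
generate_reflected_walk <- function(n_samples, reflect_limit = 10, seed = NULL,
                                    steps = NULL) {
  if (n_samples < 1) stop("n_samples must be >= 1")
  if (reflect_limit <= 0) stop("reflect_limit must be positive")
  if (is.null(steps)) {
    maybe_seed(seed)
    steps <- stats::rnorm(n_samples)
  } else {
    if (length(steps) != n_samples) stop("steps length must equal n_samples")
  }
  walk <- numeric(n_samples)
  cur <- 0
  for (i in seq_len(n_samples)) {
    st <- steps[i]
    if (abs(cur + st) > reflect_limit) st <- -st
    if (abs(cur + st) > reflect_limit) {
      cur <- sign(cur + st) * reflect_limit
    } else {
      cur <- cur + st
    }
    walk[i] <- cur
  }
  walk
}

#' Generate the smooth white-noise stimulus and its voltage command
#'
#' Reflected random walk -> causal Butterworth low-pass (single forward pass,
#' matching a physically delivered signal) -> affine rescale into the safe
#' voltage range. The current-proportional stimulus trace is
#' `capacitance_scale` times the first difference of the command (first sample
#' zero), standardized to zero mean / unit variance with the affine constants
#' recorded in the trace's `standardization` attribute.
#'
#' @param config a [stimulus_config()].
#' @return list with elements `stimulus` (class `stimulus_trace`) and
#'   `voltage` (class `voltage_command`).
#' @export
generate_stimulus <- function(config = stimulus_config()) {
  fs <- config$sampling_rate
  if (config$cutoff >= fs / 2) stop("cutoff must be below the Nyquist frequency")
  n <- round(fs * config$duration)
  walk <- generate_reflected_walk(n, config$reflect_limit, seed = config$seed)
  bf <- signal::butter(config$filter_order, config$cutoff / (fs / 2), type = "low")
  filt <- as.numeric(signal::filter(bf, walk))
  vr <- config$voltage_range
  span <- max(filt) - min(filt)
  if (span == 0) stop("degenerate walk: constant after filtering")
  volts <- (filt - min(filt)) / span * diff(vr) + vr[1]
  raw <- config$capacitance_scale * c(0, diff(volts))
  mu <- mean(raw); sdv <- stats::sd(raw)
  std <- list(mean = mu, sd = sdv)
  stim <- stimulus_trace((raw - mu) / sdv, sampling_rate = fs, standardization = std)
  attr(stim, "seed") <- config$seed
  voltage <- structure(volts, sampling_rate = fs,
                       capacitance_scale = config$capacitance_scale,
                       voltage_range = vr, seed = config$seed,
                       class = "voltage_command")
  list(stimulus = stim, voltage = voltage)
}

#' @export
print.voltage_command <- function(x, ...) {
  cat(sprintf("<voltage_command: %d samples at %g Hz, range [%.3f, %.3f] V>\n",
              length(x), attr(x, "sampling_rate"), min(x), max(x)))
  invisible(x)
}

#' Reconstruct the voltage command from a standardized stimulus trace
#'
#' Inverts the standardization and integrates, so
#' `stimulus_to_voltage(stim)[k] == volts[k] - volts[1]` up to round-off.
#' Used to assert the current/voltage consistency contract.
#'
#' @param stimulus a `stimulus_trace` with a `standardization` attribute.
#' @param capacitance_scale proportionality constant used at generation.
#' @return numeric vector: the voltage command relative to its first sample.
#' @export
stimulus_to_voltage <- function(stimulus, capacitance_scale = 1) {
  std <- attr(stimulus, "standardization")
  if (is.null(std)) stop("stimulus has no standardization metadata")
  raw <- as_samples(stimulus) * std$sd + std$mean
  cumsum(raw / capacitance_scale)
}

#' Band-power ratio of a trace (median periodogram power)
#'
#' Ratio of median power spectral density in `band_hi` to median PSD in
#' `band_lo`. The stimulus spectral contract is that power above the 100 Hz
#' cutoff falls well below the passband (ratio < 0.1).
#'
#' @param x numeric trace (a `stimulus_trace` or plain vector).
#' @param sampling_rate Hz; taken from the trace attribute when present.
#' @param band_lo,band_hi two-element frequency bands in Hz.
#' @return scalar ratio median(PSD in band_hi) / median(PSD in band_lo).
#' @export
band_power_ratio <- function(x, sampling_rate = NULL,
                             band_lo = c(10, 90), band_hi = c(110, 500)) {
  fs <- if (is.null(sampling_rate)) stim_rate(x) else sampling_rate
  sp <- stats::spec.pgram(stats::ts(as_samples(x), frequency = fs),
                          plot = FALSE, taper = 0.1)
  lo <- sp$spec[sp$freq >= band_lo[1] & sp$freq <= band_lo[2]]
  hi <- sp$spec[sp$freq >= band_hi[1] & sp$freq <= band_hi[2]]
  stats::median(hi) / stats::median(lo)
}
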