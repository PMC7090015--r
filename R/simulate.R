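## Synthetic data with known ground truth: LNP spiking, artefact-contaminated
## raw traces and light-flash responses.

#' Simulate Bernoulli spike trains from a ground-truth LNP neuron
#'
#' For every 1-ms bin with a full -20 ... +10 ms stimulus window, the spike
#' probability is the neuron's static nonlinearity applied to the (unit-SD
#' scaled) filter projection; each repetition draws one Bernoulli trial per
#' bin. Spikes are stamped at the bin start time.
#'
#' @param neuron an [lnp_neuron()]; calibrated on `stimulus` automatically if
#'   its free offset is still unset.
#' @param stimulus the driving `stimulus_trace`.
#' @param bin bin width in ms (default 1).
#' @param n_repetitions number of repetitions (default 5).
#' @param seed integer seed.
#' @return list of [spike_train()] objects, one per repetition, with the
#'   per-bin probabilities in attribute `mu` and bin indices in `bins`.
#' @export
simulate_lnp_spikes <- function(neuron, stimulus, bin = 1, n_repetitions = 5,
                                seed = NULL) {
  fs <- stim_rate(stimulus)
  if (is.na(neuron$projection_sd) ||
      (neuron$nonlinearity_kind == "sigmoid" && is.na(neuron$nonlinearity_params$x0)) ||
      (neuron$nonlinearity_kind == "exponential" && is.na(neuron$nonlinearity_params$a))) {
    neuron <- calibrate_neuron(neuron, stimulus)
  }
  anchors <- valid_bin_anchors(length(stimulus), fs, bin)
  if (!length(anchors)) stop("stimulus too short for one snippet window")
  X <- snippet_matrix(as_samples(stimulus), anchors)
  z <- as.numeric(X %*% as.numeric(neuron$filter)) / neuron$projection_sd
  mu <- apply_nonlinearity(neuron$nonlinearity_kind, z, neuron$nonlinearity_params)
  if (any(mu < 0 | mu > 1))
    stop("nonlinearity produced probabilities outside [0, 1]")
  bins <- anchors / round(fs * bin / 1000)   # 0-based bin indices
  maybe_seed(seed)
  duration <- length(stimulus) / fs
  out <- vector("list", n_repetitions)
  for (r in seq_len(n_repetitions)) {
    hit <- stats::rbinom(length(mu), 1L, mu) == 1L
    tr <- spike_train(bins[hit] * bin / 1000, repetition_id = r,
                      duration = duration)
    out[[r]] <- tr
  }
  attr(out, "mu") <- mu
  attr(out, "bins") <- bins
  attr(out, "neuron") <- neuron
  out
}

#' Default biphasic extracellular spike template
#'
#' 1 ms biphasic waveform (negative then positive lobe) at the stimulus
#' sampling rate, peak magnitude `amplitude`.
#'
#' @param amplitude peak magnitude (default 1).
#' @param sampling_rate Hz.
#' @return numeric vector of `sampling_rate / 1000` samples.
#' @export
spike_template <- function(amplitude = 1, sampling_rate = 10000) {
  n <- round(sampling_rate / 1000)
  t <- (seq_len(n) - 0.5) / n           # (0, 1) ms
  w <- -sin(2 * pi * t) * exp(-((t - 0.35) / 0.45)^2)
  amplitude * w / max(abs(w))
}

#' Synthesize an artefact-dominated raw recording
#'
#' Raw trace = `artefact_gain * stimulus` + a spike waveform inserted at each
#' spike time + Gaussian noise. With the defaults the artefact RMS exceeds
#' the spike-template peak by a factor >= 10 (the regime in which the
#' stimulation artefact masks spiking activity by orders of magnitude).
#'
#' @param stimulus the `stimulus_trace` that was delivered.
#' @param spikes a [spike_train()] (or numeric spike times in seconds).
#' @param artefact_gain nonnegative scale of the stimulus leak (default 100).
#' @param template spike waveform (default [spike_template()]).
#' @param noise_sd SD of additive Gaussian noise (default 0.05).
#' @param seed integer seed for the noise.
#' @return numeric trace of class `raw_trace` with the stimulus sampling rate.
#' @export
synthesize_raw_recording <- function(stimulus, spikes, artefact_gain = 100,
                                     template = NULL, noise_sd = 0.05,
                                     seed = NULL) {
  if (artefact_gain < 0) stop("artefact_gain must be nonnegative")
  fs <- stim_rate(stimulus)
  n <- length(stimulus)
  if (is.null(template)) template <- spike_template(sampling_rate = fs)
  times <- as.numeric(spikes)
  if (length(times) && (min(times) < 0 || max(times) * fs > n))
    stop("spikes outside the stimulus duration")
  raw <- artefact_gain * as_samples(stimulus)
  for (tm in times) {
    i0 <- round(tm * fs)                      # 0-based insertion sample
    idx <- i0 + seq_along(template)           # 1-based
    keep <- idx >= 1 & idx <= n
    raw[idx[keep]] <- raw[idx[keep]] + template[keep]
  }
  if (noise_sd > 0) {
    maybe_seed(seed)
    raw <- raw + stats::rnorm(n, sd = noise_sd)
  }
  structure(raw, sampling_rate = fs, class = "raw_trace")
}

#' @export
print.raw_trace <- function(x, ...) {
  cat(sprintf("<raw_trace: %d samples at %g Hz, RMS %.3g>\n",
              length(x), attr(x, "sampling_rate"), sqrt(mean(unclass(x)^2))))
  invisible(x)
}

## --- light responses --------------------------------------------------------

## Expected transiency index of an exponentially decaying rate over the
## 10 x 50 ms bins of the 500 ms preferred window.
ti_of_tau <- function(tau) {
  edges <- seq(0, 0.5, by = 0.05)
  h <- exp(-edges[-11] / tau) - exp(-edges[-1] / tau)
  1 - mean(h / max(h))
}

## Solve for the decay constant giving a requested transiency index.
tau_for_transiency <- function(ti) {
  if (ti <= 1e-6) return(Inf)
  if (ti >= 0.9 - 1e-9) return(0)   # delta-like: all mass in the first bin
  exp(stats::uniroot(function(lt) ti_of_tau(exp(lt)) - ti,
                     c(log(1e-4), log(100)), tol = 1e-10)$root)
}

#' Generate light-flash spike responses with a requested profile
#'
#' Inhomogeneous Poisson spike trains over repeated 1 s flash cycles (light ON
#' during the first 500 ms, OFF during the second 500 ms). The firing rate in
#' the preferred phase(s) decays exponentially from phase onset with a decay
#' constant solved so the expected transiency index matches `transiency`; the
#' non-preferred phase is silent apart from an optional baseline.
#'
#' @param polarity `"ON"`, `"OFF"` or `"ON-OFF"`.
#' @param transiency requested transiency index in \[0, 0.9\].
#' @param n_trials number of 1 s cycles (default 10).
#' @param rate mean firing rate during each preferred 500 ms window in
#'   spikes/s (default 50).
#' @param baseline_rate rate outside preferred windows (default 0).
#' @param seed integer seed.
#' @return list of [spike_train()] objects, one per trial (cycle), each over
#'   \[0, 1\) s with light onset at 0 s and offset at 0.5 s.
#' @export
generate_light_responses <- function(polarity = c("ON", "OFF", "ON-OFF"),
                                     transiency = 0.5, n_trials = 10,
                                     rate = 50, baseline_rate = 0,
                                     seed = NULL) {
  polarity <- match.arg(polarity)
  if (transiency < 0 || transiency > 0.9)
    stop("transiency must lie in [0, 0.9]")
  tau <- tau_for_transiency(transiency)
  dt <- 0.001
  tgrid <- seq(0, 0.5 - dt, by = dt)
  shape <- if (is.infinite(tau)) rep(1, length(tgrid))
           else if (tau == 0) c(rep(1, 50), rep(0, length(tgrid) - 50))
           else exp(-tgrid / tau)
  ## scale so the window-mean rate equals `rate`
  shape <- shape / mean(shape) * rate
  lam <- rep(baseline_rate, 1000)
  if (polarity %in% c("ON", "ON-OFF")) lam[1:500] <- lam[1:500] + shape
  if (polarity %in% c("OFF", "ON-OFF")) lam[501:1000] <- lam[501:1000] + shape
  maybe_seed(seed)
  out <- vector("list", n_trials)
  for (tr in seq_len(n_trials)) {
    counts <- stats::rpois(1000, lam * dt)
    times <- rep((seq_len(1000) - 1) * dt, counts) +
      stats::runif(sum(counts), 0, dt)
    out[[tr]] <- spike_train(sort(times), repetition_id = tr, duration = 1)
  }
  attr(out, "profile") <- list(polarity = polarity, transiency = transiency,
                               rate = rate)
  out
}
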