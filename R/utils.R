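## Shared internal helpers and light S3 constructors.
##
## Conventions used throughout the package:
##   * sampling rate 10 kHz, spike bins of 1 ms (10 samples per bin)
##   * filter window -20 ms ... +10 ms around the spike: 300 taps at 0.1 ms,
##     tap k (1-based) sits at (k - 201) * 0.1 ms
##   * sample indexing is 0-based in all index arithmetic; conversion to R's
##     1-based subsetting happens at the last moment
##   * spike bins are half-open [t, t + 1 ms); a spike exactly on a bin edge
##     belongs to the later bin

FILTER_TAPS <- 300L
TAPS_PAST <- 200L    # samples before the bin anchor
TAPS_FUTURE <- 100L  # samples from the anchor onwards (anchor included)

#' Tap times of the temporal filter window
#'
#' @param sampling_rate samples per second of the stimulus (default 10 kHz).
#' @return Numeric vector of length 300: times in ms relative to the spike,
#'   from -20.0 to +9.9 in 0.1 ms steps at the default rate.
#' @export
filter_tap_times <- function(sampling_rate = 10000) {
  dt <- 1000 / sampling_rate
  (seq_len(FILTER_TAPS) - TAPS_PAST - 1) * dt
}

#' Cosine similarity between two vectors
#'
#' @param a,b numeric vectors of equal length.
#' @return scalar in \[-1, 1\].
#' @export
cosine_similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  sum(a * b) / (na * nb)
}

## --- stimulus trace ---------------------------------------------------------

#' Construct a stimulus trace
#'
#' A stimulus trace is a numeric vector of current-proportional samples with a
#' sampling-rate attribute. Traces produced by [generate_stimulus()] are
#' standardized to zero mean and unit variance; the affine constants are kept
#' in the `standardization` attribute so the voltage command can be
#' reconstructed.
#'
#' @param samples numeric vector, finite values.
#' @param sampling_rate Hz.
#' @param standardization optional list with elements `mean` and `sd` of the
#'   raw (pre-standardization) trace.
#' @return object of class `stimulus_trace`.
#' @export
stimulus_trace <- function(samples, sampling_rate = 10000, standardization = NULL) {
  samples <- as.numeric(samples)
  if (any(!is.finite(samples))) stop("stimulus samples must be finite")
  structure(samples, sampling_rate = sampling_rate,
            standardization = standardization, class = "stimulus_trace")
}

#' @export
print.stimulus_trace <- function(x, ...) {
  cat(sprintf("<stimulus_trace: %d samples at %g Hz (%.3f s)>\n",
              length(x), attr(x, "sampling_rate"),
              length(x) / attr(x, "sampling_rate")))
  invisible(x)
}

stim_rate <- function(x, default = 10000) {
  r <- attr(x, "sampling_rate")
  if (is.null(r)) default else r
}

## strip class/attrs for raw arithmetic
as_samples <- function(x) as.numeric(unclass(x))

## --- spike train ------------------------------------------------------------

#' Construct a spike train
#'
#' @param times spike times in seconds, sorted ascending.
#' @param repetition_id integer repetition label.
#' @param cell_id cell identifier.
#' @param duration recording duration in seconds (optional metadata).
#' @return object of class `spike_train`.
#' @export
spike_train <- function(times, repetition_id = 1L, cell_id = "cell", duration = NA_real_) {
  times <- as.numeric(times)
  if (is.unsorted(times)) stop("spike times must be sorted ascending")
  if (!is.na(duration) && length(times) &&
      (min(times) < 0 || max(times) > duration)) {
    stop("spike times outside [0, duration]")
  }
  structure(times, repetition_id = as.integer(repetition_id),
            cell_id = cell_id, duration = duration, class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train '%s' rep %d: %d spikes%s>\n",
              attr(x, "cell_id"), attr(x, "repetition_id"), length(x),
              if (is.na(attr(x, "duration"))) ""
              else sprintf(" in %.3f s", attr(x, "duration"))))
  invisible(x)
}

## Coerce a spike train (or plain numeric of times) to a list of trains.
as_train_list <- function(spikes) {
  if (inherits(spikes, "spike_train") || (is.numeric(spikes) && !is.list(spikes)))
    spikes <- list(spikes)
  lapply(spikes, as.numeric)
}

## Map spike times (s) to 0-based 1-ms bin indices, exactly on the microsecond
## grid so edge spikes land in the later bin.
spike_bins <- function(times, bin_ms = 1) {
  us <- round(times * 1e6)
  as.integer(us %/% round(bin_ms * 1000))
}

## Pooled (or per-repetition) spike counts per 1-ms bin over n_bins bins.
bin_spike_counts <- function(trains, n_bins, bin_ms = 1) {
  counts <- integer(n_bins)
  for (tr in trains) {
    b <- spike_bins(tr, bin_ms)
    b <- b[b >= 0 & b < n_bins]
    if (length(b)) {
      tb <- tabulate(b + 1L, nbins = n_bins)
      counts <- counts + tb
    }
  }
  counts
}

## --- seeds ------------------------------------------------------------------

#' Derive a child seed from a master seed
#'
#' Deterministic counter-based derivation so one master seed funnels into all
#' stochastic stages while keeping stages decoupled. The result is kept within
#' the 32-bit integer range.
#'
#' @param master integer master seed.
#' @param counter stage counter (integer >= 0).
#' @return integer child seed.
#' @export
derive_seed <- function(master, counter) {
  x <- (as.double(master) %% 2147483647) + 1
  for (i in seq_len(counter + 1)) {
    x <- (x * 48271) %% 2147483647
  }
  as.integer(x)
}

## set seed only when one is supplied
maybe_seed <- function(seed) {
  if (!is.null(seed) && !is.na(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}
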