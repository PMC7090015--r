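## Response reliability and light-response profile metrics.

#' Reliability index across stimulus repetitions
#'
#' Bins every repetition into `bin`-ms histograms over `[0, duration)`. For
#' each leave-one-out split, the pooled histogram of the held-in repetitions
#' (H) is correlated (Pearson) with the held-out repetition's histogram (h);
#' the reliability index is the mean correlation over all n splits. 1 means
#' identical response patterns in every repetition; values near 0 mean no
#' repeatable structure. If any split involves a zero-variance histogram the
#' index is NaN with the degenerate flag set.
#'
#' @param trials list of [spike_train()] objects (>= 2 repetitions).
#' @param duration recording duration in seconds (taken from the trains when
#'   available).
#' @param bin histogram bin width in ms (default 2).
#' @return list of class `reliability_result`: `ri`, `bin`, `n_repetitions`,
#'   `degenerate` flag and the per-split correlations.
#' @export
reliability_index <- function(trials, duration = NULL, bin = 2) {
  trials <- as_train_list(trials)
  n <- length(trials)
  if (n < 2) stop("reliability requires at least 2 repetitions")
  if (is.null(duration)) {
    durs <- vapply(trials, function(t) {
      d <- attr(t, "duration"); if (is.null(d)) NA_real_ else d
    }, 0)
    duration <- if (all(is.na(durs))) max(unlist(trials), 0) else max(durs, na.rm = TRUE)
  }
  n_bins <- ceiling(duration * 1000 / bin)
  H <- vapply(trials, function(t) {
    b <- spike_bins(t, bin_ms = bin)
    tabulate(b[b >= 0 & b < n_bins] + 1L, nbins = n_bins)
  }, integer(n_bins))
  total <- rowSums(H)
  cors <- vapply(seq_len(n), function(i) {
    h <- H[, i]
    pooled <- total - h
    if (stats::sd(h) == 0 || stats::sd(pooled) == 0) return(NA_real_)
    stats::cor(pooled, h)
  }, 0)
  degenerate <- anyNA(cors)
  structure(list(ri = if (degenerate) NaN else mean(cors),
                 bin = bin, n_repetitions = n,
                 degenerate = degenerate, split_correlations = cors),
            class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("Reliability index: %s (%d repetitions, %g ms bins)%s\n",
              format(x$ri, digits = 4), x$n_repetitions, x$bin,
              if (x$degenerate) " [degenerate variance]" else ""))
  invisible(x)
}

#' Reliability inclusion criterion
#'
#' TRUE iff the reliability index strictly exceeds the threshold (cells with
#' RI > 0.15 are considered reliably responding).
#'
#' @param result a [reliability_index()] result (or a bare RI value).
#' @param threshold default 0.15.
#' @return logical.
#' @export
classify_reliable <- function(result, threshold = 0.15) {
  ri <- if (inherits(result, "reliability_result")) result$ri else as.numeric(result)
  if (is.na(ri)) {
    warning("reliability index is NaN; classifying as unreliable")
    return(FALSE)
  }
  ri > threshold
}

count_in_windows <- function(trials, starts, window_s) {
  total <- 0L
  for (tr in trials) {
    t <- as.numeric(tr)
    for (s0 in starts) total <- total + sum(t >= s0 & t < s0 + window_s)
  }
  total
}

#' Bias index of a light response
#'
#' `BI = (R_ON - R_OFF) / (R_ON + R_OFF)` with R_ON and R_OFF the total spike
#' counts in the first `window` ms after light onset and offset, summed over
#' repetitions. Classification: `BI < -0.25` OFF, `-0.25 <= BI <= 0.5` ON-OFF,
#' `BI > 0.5` ON.
#'
#' @param trials list of [spike_train()] objects (one per repetition/cycle).
#' @param onset_times light-onset times in seconds (default 0).
#' @param offset_times light-offset times in seconds (default 0.5).
#' @param window counting window in ms (default 300).
#' @return list of class `light_response_metrics` with `bias_index`, `r_on`,
#'   `r_off`, `polarity_class` and an `undefined` flag.
#' @export
bias_index <- function(trials, onset_times = 0, offset_times = 0.5,
                       window = 300) {
  trials <- as_train_list(trials)
  w <- window / 1000
  r_on <- count_in_windows(trials, onset_times, w)
  r_off <- count_in_windows(trials, offset_times, w)
  if (r_on + r_off == 0) {
    return(structure(list(bias_index = NaN, r_on = r_on, r_off = r_off,
                          polarity_class = NA_character_, undefined = TRUE),
                     class = "light_response_metrics"))
  }
  bi <- (r_on - r_off) / (r_on + r_off)
  cls <- if (bi < -0.25) "OFF" else if (bi <= 0.5) "ON-OFF" else "ON"
  structure(list(bias_index = bi, r_on = r_on, r_off = r_off,
                 polarity_class = cls, undefined = FALSE),
            class = "light_response_metrics")
}

## transiency of one phase: trial-summed histogram over the window following
## each event, normalized by its maximum bin
phase_transiency <- function(trials, events, window_s, bin_s) {
  n_bins <- round(window_s / bin_s)
  h <- numeric(n_bins)
  for (tr in trials) {
    t <- as.numeric(tr)
    for (e in events) {
      rel <- t[t >= e & t < e + window_s] - e
      if (length(rel)) h <- h + tabulate(floor(rel / bin_s) + 1L, nbins = n_bins)
    }
  }
  if (sum(h) == 0) return(NaN)
  1 - mean(h / max(h))
}

#' Transiency index of a light response
#'
#' 1 minus the mean of the max-normalized trial-summed histogram (`bin` ms
#' bins) over the `window` ms following each preferred stimulus event: 0 for a
#' perfectly sustained response, `1 - 1/n_bins` (0.9 with the defaults) for a
#' response confined to the first bin. For ON-OFF cells pass both phases'
#' event times; the index is the mean of the per-phase indices.
#'
#' @param trials list of [spike_train()] objects.
#' @param preferred_events event times in seconds, or a list of one or two
#'   numeric vectors (one per phase for ON-OFF cells).
#' @param window window length in ms (default 500).
#' @param bin histogram bin in ms (default 50).
#' @return list of class `light_response_metrics` with `transiency_index` and
#'   an `undefined` flag.
#' @export
transiency_index <- function(trials, preferred_events = 0, window = 500,
                             bin = 50) {
  trials <- as_train_list(trials)
  if (!is.list(preferred_events)) preferred_events <- list(preferred_events)
  tis <- vapply(preferred_events, function(ev)
    phase_transiency(trials, ev, window / 1000, bin / 1000), 0)
  structure(list(transiency_index = mean(tis), per_phase = tis,
                 undefined = anyNA(tis)),
            class = "light_response_metrics")
}

#' @export
print.light_response_metrics <- function(x, ...) {
  if (!is.null(x$bias_index))
    cat(sprintf("Bias index: %s (R_ON %d, R_OFF %d) -> %s\n",
                format(x$bias_index, digits = 4), x$r_on, x$r_off,
                if (is.na(x$polarity_class)) "undefined" else x$polarity_class))
  if (!is.null(x$transiency_index))
    cat(sprintf("Transiency index: %s\n", format(x$transiency_index, digits = 4)))
  invisible(x)
}

#' Combined light-response profile
#'
#' Classifies polarity from the bias index, then computes the transiency
#' index over the preferred phase(s): onset events for ON cells, offset events
#' for OFF cells, both (averaged) for ON-OFF cells.
#'
#' @inheritParams bias_index
#' @param ti_window,ti_bin transiency window and bin in ms.
#' @return `light_response_metrics` with both indices and the class label.
#' @export
light_response_metrics <- function(trials, onset_times = 0, offset_times = 0.5,
                                   window = 300, ti_window = 500, ti_bin = 50) {
  bi <- bias_index(trials, onset_times, offset_times, window)
  events <- switch(ifelse(is.na(bi$polarity_class), "NA", bi$polarity_class),
                   ON = list(onset_times),
                   OFF = list(offset_times),
                   `ON-OFF` = list(onset_times, offset_times),
                   `NA` = list(onset_times, offset_times))
  ti <- transiency_index(trials, events, ti_window, ti_bin)
  out <- c(bi[c("bias_index", "r_on", "r_off", "polarity_class", "undefined")],
           ti[c("transiency_index", "per_phase")])
  out$undefined <- bi$undefined || ti$undefined
  structure(out, class = "light_response_metrics")
}
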