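## Firing-rate prediction and blockwise cross-validation.

#' Firing-rate prediction from a fitted model
#'
#' Thin functional wrapper over [predict.lnp()] (rate at 1 kHz).
#'
#' @param model a fitted [lnp()] model.
#' @param stimulus a `stimulus_trace`.
#' @return numeric vector, one per-repetition spike probability per 1-ms bin
#'   (`NA` at bins without a full stimulus window).
#' @export
predict_firing_rate <- function(model, stimulus = NULL) {
  predict(model, stimulus, type = "rate")
}

#' Linear-stage prediction
#'
#' Dot product of the filter with every 1-ms stimulus window, without the
#' static nonlinearity. Can be negative; correlation-based scoring is
#' unaffected by scale or offset.
#'
#' @param filter a [linear_filter()] or a fitted [lnp()] model (whose
#'   model-consistent stimulus space is then used).
#' @param stimulus a `stimulus_trace`.
#' @return numeric vector at 1 kHz with `NA` at boundary bins.
#' @export
linear_stage_prediction <- function(filter, stimulus) {
  if (inherits(filter, "lnp")) return(predict(filter, stimulus, type = "linear"))
  fs <- stim_rate(stimulus)
  stride <- round(fs / 1000)
  anchors <- valid_bin_anchors(length(stimulus), fs)
  out <- rep(NA_real_, length(stimulus) %/% stride)
  out[anchors / stride + 1L] <-
    as.numeric(snippet_matrix(as_samples(stimulus), anchors) %*% as.numeric(filter))
  out
}

#' Prediction performance (correlation at 1 kHz)
#'
#' Pearson correlation between the true and predicted firing-rate vectors;
#' bins missing in either vector are excluded pairwise. Returns NaN with the
#' degenerate flag when either vector has zero variance.
#'
#' @param true_rate,predicted_rate equal-length numeric vectors.
#' @return scalar of class `prediction_performance` (plain numeric with a
#'   `degenerate` attribute).
#' @export
prediction_performance <- function(true_rate, predicted_rate) {
  if (length(true_rate) != length(predicted_rate))
    stop("true and predicted rates must have equal length")
  ok <- is.finite(true_rate) & is.finite(predicted_rate)
  x <- true_rate[ok]; y <- predicted_rate[ok]
  if (length(x) < 2) stop("need at least 2 paired bins")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(structure(NaN, degenerate = TRUE))
  }
  structure(stats::cor(x, y), degenerate = FALSE)
}

#' Blockwise cross-validation plan
#'
#' @param n_splits number of folds (default 5).
#' @param test_span seconds of held-out data per fold (default 1).
#' @param train_span seconds of training data per fold (default 4).
#' @return list of class `cv_plan`.
#' @export
cv_plan <- function(n_splits = 5, test_span = 1, train_span = 4) {
  structure(list(n_splits = n_splits, test_span = test_span,
                 train_span = train_span), class = "cv_plan")
}

#' Blockwise cross-validated prediction
#'
#' For each of the `n_splits` contiguous test blocks, fits the model on the
#' remaining training seconds (pooling repetitions; training bins whose
#' -20 ... +10 ms window crosses a block seam are dropped so no snippet mixes
#' train and test stimulus segments around training labels) and predicts the
#' held-out block. The true rate is the spike count per 1-ms bin summed
#' across repetitions.
#'
#' @param stimulus the full `stimulus_trace`.
#' @param spikes list of [spike_train()] repetitions.
#' @param method `"sta"` or `"mle"`.
#' @param plan a [cv_plan()].
#' @param linear_only also score the linear-stage prediction?
#' @param ... passed to [lnp()].
#' @return data.frame of class `blockwise_cv` with one row per split:
#'   `split`, `method`, `performance`, and `performance_linear` when
#'   requested; mean performance in attribute `mean_performance`, per-split
#'   predictions in attribute `details`.
#' @export
run_blockwise_cv <- function(stimulus, spikes, method = c("sta", "mle"),
                             plan = cv_plan(), linear_only = FALSE, ...) {
  method <- match.arg(method)
  fs <- stim_rate(stimulus)
  dur <- length(stimulus) / fs
  if (abs(dur - plan$n_splits * plan$test_span) > 1e-9)
    stop("recording duration must equal n_splits * test_span")
  trains <- as_train_list(spikes)
  stride <- round(fs / 1000)
  n_bins_total <- length(stimulus) %/% stride
  true_rate <- bin_spike_counts(trains, n_bins_total)
  bins_ms_per_block <- round(plan$test_span * 1000)
  guard <- 30L  # ms: half-window span over which a snippet can touch a seam
  rows <- list(); details <- list()
  for (k in seq_len(plan$n_splits)) {
    test_lo <- (k - 1L) * bins_ms_per_block          # 0-based ms bins
    test_hi <- test_lo + bins_ms_per_block - 1L
    all_bins <- 0:(n_bins_total - 1L)
    in_test <- all_bins >= test_lo & all_bins <= test_hi
    near_seam <- (all_bins >= test_lo - guard & all_bins < test_lo) |
      (all_bins > test_hi & all_bins <= test_hi + guard)
    train_bins <- all_bins[!in_test & !near_seam]
    fit <- lnp(stimulus, trains, method = method, bins = train_bins, ...)
    pred <- predict(fit, stimulus, type = "rate")
    idx <- which(in_test)
    perf <- prediction_performance(true_rate[idx], pred[idx])
    row <- data.frame(split = k, method = toupper(method),
                      performance = as.numeric(perf),
                      degenerate = isTRUE(attr(perf, "degenerate")))
    det <- list(test_bins = all_bins[in_test], predicted = pred[idx],
                true = true_rate[idx])
    if (linear_only) {
      lin <- predict(fit, stimulus, type = "linear")
      lp <- prediction_performance(true_rate[idx], lin[idx])
      row$performance_linear <- as.numeric(lp)
      det$linear <- lin[idx]
    }
    rows[[k]] <- row; details[[k]] <- det
  }
  out <- do.call(rbind, rows)
  attr(out, "mean_performance") <- mean(out$performance, na.rm = TRUE)
  if (linear_only)
    attr(out, "mean_performance_linear") <- mean(out$performance_linear, na.rm = TRUE)
  attr(out, "details") <- details
  attr(out, "plan") <- plan
  class(out) <- c("blockwise_cv", "data.frame")
  out
}

#' @export
print.blockwise_cv <- function(x, ...) {
  print.data.frame(x, row.names = FALSE)
  cat(sprintf("mean performance: %.3f\n", attr(x, "mean_performance")))
  invisible(x)
}
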