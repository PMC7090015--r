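## Stimulus snippet geometry and whitening.
##
## The 5 s, 50 000-sample stimulus is sliced into 300-sample snippets taken 10
## samples (1 ms) apart: the "full ensemble" of 4971 rows. Each 1-ms spike bin
## t is anchored at sample a = 10 t (0-based); its snippet spans samples
## a - 200 ... a + 99, i.e. -20 ... +10 ms around the bin. Bins whose window
## exits the trace are excluded everywhere (simulation, STA, GLM, prediction).

## 0-based anchor samples of all bins with a full window inside n samples
valid_bin_anchors <- function(n_samples, sampling_rate = 10000, bin_ms = 1) {
  stride <- round(sampling_rate * bin_ms / 1000)
  a <- seq.int(TAPS_PAST, n_samples - TAPS_FUTURE, by = stride)
  a[a >= TAPS_PAST & a <= n_samples - TAPS_FUTURE]
}

## design matrix: one row per 0-based anchor, columns = 300 window samples
snippet_matrix <- function(samples, anchors) {
  idx <- outer(as.integer(anchors), (-TAPS_PAST):(TAPS_FUTURE - 1L), "+") + 1L
  matrix(samples[idx], nrow = length(anchors))
}

#' Slice a stimulus into the full snippet ensemble
#'
#' Rows are `stimulus[i * stride + 1 : i * stride + length]` (0-based starts),
#' giving `floor((n - length) / stride) + 1` rows.
#'
#' @param stimulus a `stimulus_trace` or numeric vector.
#' @param length snippet length in samples (default 300).
#' @param stride spacing between snippet starts in samples (default 10).
#' @return object of class `snippet_ensemble`: a numeric matrix with
#'   attributes `stride`, `starts` (0-based start samples) and
#'   `sampling_rate`.
#' @export
extract_snippets <- function(stimulus, length = 300L, stride = 10L) {
  s <- as_samples(stimulus)
  n <- base::length(s)
  if (n < length) stop("stimulus shorter than one snippet")
  starts <- seq.int(0L, n - length, by = stride)
  idx <- outer(starts, seq_len(length) - 1L, "+") + 1L
  structure(matrix(s[idx], nrow = base::length(starts)),
            stride = stride, starts = starts,
            sampling_rate = stim_rate(stimulus),
            class = c("snippet_ensemble", "matrix"))
}

#' Whitening operator from the snippet covariance
#'
#' Eigendecomposes the ensemble covariance and forms the square root of its
#' pseudo-inverse: eigenvalues above the retention threshold are inverted and
#' square-rooted, the remainder set to zero. The retained rank limits how
#' strongly the deeply suppressed above-cutoff stimulus modes are amplified.
#'
#' @param ensemble a [extract_snippets()] result (or plain matrix of rows).
#' @param retention either a relative eigenvalue tolerance (default `1e-7`:
#'   keep eigenvalues `>= 1e-7 * lambda_max`, which for the default stimulus
#'   equalizes modes out to roughly 500 Hz and decorrelates the whitened
#'   trace at millisecond lags) or an integer rank `L`.
#' @return object of class `whitening_operator`: the 300 x 300 symmetric
#'   matrix with attributes `rank`, `eigen_spectrum` (retained eigenvalues)
#'   and `retention_rule`.
#' @export
compute_whitening_operator <- function(ensemble, retention = 1e-7) {
  X <- unclass(ensemble)
  if (all(X == 0)) stop("degenerate input: all-zero snippet ensemble")
  if (nrow(X) < ncol(X))
    warning("fewer snippets than dimensions; covariance estimate is rank-deficient")
  C <- stats::cov(X)
  e <- eigen(C, symmetric = TRUE)
  lam <- e$values
  if (is.numeric(retention) && retention >= 1 && retention == round(retention)) {
    L <- min(as.integer(retention), sum(lam > 0))
    rule <- sprintf("fixed rank L = %d", L)
  } else {
    L <- sum(lam >= retention * lam[1])
    rule <- sprintf("relative tolerance: lambda >= %g * lambda_max", retention)
  }
  if (L < 1) stop("no eigenvalues retained")
  V <- e$vectors[, seq_len(L), drop = FALSE]
  W <- V %*% (t(V) / sqrt(lam[seq_len(L)]))
  structure(W, rank = L, eigen_spectrum = lam[seq_len(L)],
            retention_rule = rule, class = c("whitening_operator", "matrix"))
}

#' @export
print.whitening_operator <- function(x, ...) {
  cat(sprintf("<whitening_operator: rank %d / %d (%s)>\n",
              attr(x, "rank"), ncol(x), attr(x, "retention_rule")))
  invisible(x)
}

#' Whiten a stimulus trace by snippet-wise decorrelation
#'
#' Each stride-spaced snippet is multiplied by the whitening operator; the
#' overlapping whitened snippets are then blended back into a single trace by
#' overlap-add with tapered (Hann) weights, normalized to unity at every
#' covered sample. A strictly positive "periodic" Hann taper is used so every
#' covered sample has nonzero total weight; with the identity operator the
#' reconstruction returns the input exactly. Samples not covered by any full
#' snippet (none for the default 50 000-sample geometry) are left unchanged.
#'
#' @param stimulus a `stimulus_trace` or numeric vector.
#' @param operator a [compute_whitening_operator()] result.
#' @param stride snippet spacing in samples (default 10).
#' @return whitened trace of the same length and class as the input.
#' @export
whiten_stimulus <- function(stimulus, operator, stride = 10L) {
  s <- as_samples(stimulus)
  L <- ncol(operator)
  n <- length(s)
  if (n < L) stop("stimulus shorter than the snippet geometry")
  starts <- seq.int(0L, n - L, by = stride)   # 0-based
  ## all whitened snippets in one multiply: L x n_snippets
  idx <- outer(seq_len(L) - 1L, starts, "+") + 1L
  S <- matrix(s[idx], nrow = L)
  SW <- unclass(operator) %*% S
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(L) - 0.5) / L)  # > 0 everywhere
  num <- numeric(n); den <- numeric(n)
  for (j in seq_along(starts)) {
    rng <- (starts[j] + 1L):(starts[j] + L)
    num[rng] <- num[rng] + w * SW[, j]
    den[rng] <- den[rng] + w
  }
  out <- s
  covd <- den > 0
  out[covd] <- num[covd] / den[covd]
  if (inherits(stimulus, "stimulus_trace")) {
    attributes(out) <- attributes(stimulus)
    attr(out, "whitened") <- TRUE
  }
  out
}

#' Autocorrelation of a trace at millisecond lags
#'
#' Convenience wrapper used by the whitening contract: maximum absolute
#' autocorrelation over a range of lags expressed in ms.
#'
#' @param x numeric trace.
#' @param lags_ms vector of lags in ms.
#' @param sampling_rate Hz.
#' @return named numeric vector of autocorrelations at the requested lags.
#' @export
trace_acf <- function(x, lags_ms = 1:20, sampling_rate = NULL) {
  fs <- if (is.null(sampling_rate)) stim_rate(x) else sampling_rate
  lag_samp <- round(lags_ms * fs / 1000)
  a <- stats::acf(as_samples(x), lag.max = max(lag_samp), plot = FALSE)$acf[, 1, 1]
  stats::setNames(a[lag_samp + 1], paste0(lags_ms, "ms"))
}
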