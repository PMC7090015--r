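## Spike-triggered averaging on the whitened stimulus and histogram-ratio
## nonlinearity estimation.

#' Spike-triggered average filter
#'
#' Averages the -20 ... +10 ms stimulus windows around every usable spike:
#' tap at lag tau is the mean of `stimulus[spike_sample + tau]`. Pass the
#' whitened reconstruction from [whiten_stimulus()] to obtain the
#' correlation-corrected filter. Spikes whose window exits the trace are
#' skipped and counted.
#'
#' @param stimulus the (typically whitened) `stimulus_trace`.
#' @param spikes a [spike_train()] or list of repetitions; repetitions are
#'   pooled.
#' @param sampling_rate Hz; taken from the trace attribute when present.
#' @return [linear_filter()] with method `"STA"` and attributes
#'   `n_spikes_used` / `n_spikes_skipped`.
#' @export
compute_sta <- function(stimulus, spikes, sampling_rate = NULL) {
  fs <- if (is.null(sampling_rate)) stim_rate(stimulus) else sampling_rate
  s <- as_samples(stimulus)
  n <- length(s)
  bins <- unlist(lapply(as_train_list(spikes), spike_bins))
  stride <- round(fs / 1000)
  anchors <- bins * stride
  ok <- anchors >= TAPS_PAST & anchors <= n - TAPS_FUTURE
  if (!any(ok)) stop("no usable spikes: every window exits the trace")
  X <- snippet_matrix(s, anchors[ok])
  f <- linear_filter(colMeans(X), method = "STA", sampling_rate = fs)
  attr(f, "n_spikes_used") <- sum(ok)
  attr(f, "n_spikes_skipped") <- sum(!ok)
  f
}

#' Histogram-ratio estimate of the static nonlinearity
#'
#' Projects the full snippet ensemble (FE) and the spike-triggered ensemble
#' (STE) onto the filter, histograms both on shared bin edges spanning the
#' central 99% of the FE projections, and forms the per-bin ratio
#' `H_STE / H_FE`. Bins whose FE count falls below `min_count` are masked.
#'
#' @param filter the cell's [linear_filter()].
#' @param full_ensemble FE snippets ([extract_snippets()] of the whitened
#'   stimulus for STA models).
#' @param ste STE snippets (windows around each spike, same geometry).
#' @param n_bins number of equal-width bins (default 25).
#' @param min_count minimum FE count per usable bin (default 5).
#' @return list of class `nonlinearity_estimate`: `bin_centers`, `ratio`,
#'   `h_ste`, `h_fe`, `mask` (usable bins) and counts.
#' @export
estimate_nonlinearity <- function(filter, full_ensemble, ste, n_bins = 25,
                                  min_count = 5) {
  if (NROW(ste) == 0) stop("empty spike-triggered ensemble")
  v <- as.numeric(filter)
  pf <- as.numeric(unclass(full_ensemble) %*% v)
  ps <- as.numeric(unclass(ste) %*% v)
  qs <- stats::quantile(pf, c(0.005, 0.995), names = FALSE)
  if (qs[1] == qs[2]) stop("degenerate projections: zero spread")
  edges <- seq(qs[1], qs[2], length.out = n_bins + 1)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  cut_counts <- function(x) {
    i <- findInterval(x, edges, rightmost.closed = TRUE)
    tabulate(i[i >= 1 & i <= n_bins], nbins = n_bins)
  }
  h_fe <- cut_counts(pf)
  h_ste <- cut_counts(ps)
  mask <- h_fe >= min_count
  ratio <- ifelse(mask, h_ste / pmax(h_fe, 1), NA_real_)
  structure(list(bin_centers = centers, ratio = ratio, h_ste = h_ste,
                 h_fe = h_fe, mask = mask, n_ste = length(ps),
                 n_fe = length(pf), fitted_kind = NULL, params = NULL,
                 fit_residual = NA_real_),
            class = "nonlinearity_estimate")
}

#' @export
print.nonlinearity_estimate <- function(x, ...) {
  cat(sprintf("<nonlinearity_estimate: %d/%d usable bins%s>\n",
              sum(x$mask), length(x$mask),
              if (is.null(x$fitted_kind)) ""
              else sprintf(", fitted %s (RSS %.4g)", x$fitted_kind,
                           x$fit_residual)))
  invisible(x)
}

## deterministic multi-start least squares of one parametric form
fit_nl_one <- function(x, y, kind) {
  rng <- range(x); spread <- diff(rng)
  ymin0 <- min(y); ymax0 <- max(y) - min(y)
  starts <- if (kind == "sigmoid") {
    list(list(y_max = ymax0, g = 2 / max(spread, 1e-8), x0 = stats::median(x), y_min = ymin0),
         list(y_max = ymax0, g = 5 / max(spread, 1e-8), x0 = mean(rng), y_min = ymin0),
         list(y_max = ymax0, g = 1 / max(spread, 1e-8), x0 = stats::quantile(x, 0.75, names = FALSE), y_min = ymin0),
         list(y_max = 2 * ymax0, g = 2 / max(spread, 1e-8), x0 = stats::quantile(x, 0.9, names = FALSE), y_min = ymin0),
         list(y_max = max(ymax0, 1e-6), g = 10 / max(spread, 1e-8), x0 = mean(x), y_min = 0))
  } else {
    g0 <- 1 / max(stats::sd(x), 1e-8)
    list(list(a = max(ymax0, 1e-6), g = g0, y_min = ymin0),
         list(a = max(mean(y), 1e-6), g = g0 / 2, y_min = 0),
         list(a = max(ymax0, 1e-6) / 2, g = 2 * g0, y_min = ymin0),
         list(a = max(y[which.max(x)], 1e-6), g = g0, y_min = min(y)),
         list(a = 1e-3, g = g0, y_min = mean(y)))
  }
  form <- if (kind == "sigmoid") {
    y ~ y_max / (1 + exp(-g * (x - x0))) + y_min
  } else {
    y ~ a * exp(g * x) + y_min
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(form, data = data.frame(x = x, y = y),
                                         start = st,
                                         control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop("nonlinearity fit failed to converge from any start (", kind, ")")
  list(params = as.list(stats::coef(best$fit)), rss = best$rss)
}

#' Fit a parametric form to an estimated nonlinearity
#'
#' Least-squares fit of the sigmoid (`y_max / (1 + exp(-g (x - x0))) + y_min`)
#' or exponential (`a exp(g x) + y_min`) form to the (bin center, ratio)
#' pairs, with 5 deterministic data-driven starts. When `kind = "auto"` both
#' forms are fit and the lower-residual form wins.
#'
#' @param estimate an [estimate_nonlinearity()] result.
#' @param kind `"auto"`, `"sigmoid"` or `"exponential"`.
#' @return the estimate with `fitted_kind`, `params` and `fit_residual`
#'   filled in.
#' @export
fit_nonlinearity <- function(estimate, kind = c("auto", "sigmoid", "exponential")) {
  kind <- match.arg(kind)
  x <- estimate$bin_centers[estimate$mask]
  y <- estimate$ratio[estimate$mask]
  if (length(x) < 5) stop("need at least 5 usable bins to fit the nonlinearity")
  if (stats::sd(y) < 1e-10) {
    ## flat ratio: the parametric forms degenerate to a constant offset
    estimate$fitted_kind <- if (kind == "exponential") "exponential" else "sigmoid"
    estimate$params <- if (estimate$fitted_kind == "sigmoid") {
      list(y_max = 0, g = 1, x0 = stats::median(x), y_min = mean(y))
    } else {
      list(a = 0, g = 1, y_min = mean(y))
    }
    estimate$fit_residual <- sum((y - mean(y))^2)
    return(estimate)
  }
  kinds <- if (kind == "auto") c("sigmoid", "exponential") else kind
  fits <- lapply(kinds, function(k) tryCatch(fit_nl_one(x, y, k),
                                             error = function(e) NULL))
  ok <- !vapply(fits, is.null, TRUE)
  if (!any(ok)) stop("nonlinearity fit failed for every requested form")
  rss <- vapply(fits[ok], function(f) f$rss, 0)
  pick <- which(ok)[which.min(rss)]
  estimate$fitted_kind <- kinds[pick]
  estimate$params <- fits[[pick]]$params
  estimate$fit_residual <- fits[[pick]]$rss
  estimate
}
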