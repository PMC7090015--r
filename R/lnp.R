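## The linear-nonlinear-Poisson model object.
##
## `lnp()` is the package's central fitting function. Both estimation routes
## produce the same kind of object -- a 300-tap temporal filter plus a static
## nonlinearity -- differing in how the filter is obtained (whitened
## spike-triggered average vs penalized maximum likelihood) and in the form
## of the nonlinearity (fitted sigmoid/exponential vs the logistic link).

#' Fit a linear-nonlinear-Poisson model to electrically evoked spikes
#'
#' @param stimulus the standardized `stimulus_trace` that drove the cell.
#' @param spikes a [spike_train()] or list of repetitions of the same
#'   stimulus.
#' @param method `"sta"`: whitened spike-triggered average with a
#'   histogram-ratio nonlinearity; `"mle"`: elastic-net logistic regression
#'   on raw snippets.
#' @param bins optional 0-based 1-ms bin indices to train on (used by the
#'   blockwise cross-validation; spikes outside these bins are ignored and
#'   no snippet crosses a block seam).
#' @param whitening optional precomputed [compute_whitening_operator()] (STA
#'   route); computed from the stimulus when absent.
#' @param retention eigenvalue retention rule for the whitening operator.
#' @param nonlinearity `"auto"`, `"sigmoid"` or `"exponential"` (STA route).
#' @param n_bins,min_count histogram settings for the nonlinearity estimate.
#' @param config an [elasticnet_config()] for the MLE route.
#' @param lambda,alpha fixed MLE hyperparameters; defaults to the strongest
#'   ridge corner of the grid (`lambda = 1e-2`, `alpha = 0`), the package's
#'   smoothness prior for temporal filters. Set both to `NULL` to run the
#'   cross-validated grid search.
#' @return object of class `c("lnp_sta"|"lnp_mle", "lnp")` with components
#'   `filter`, `nonlinearity`, `intercept` (MLE), `whitening` (STA),
#'   `stimulus`, `n_repetitions` and fit metadata. Supported methods:
#'   `print`, `summary`, `coef`, `predict`, `fitted`, `residuals`,
#'   `simulate`, `plot`.
#' @seealso [predict.lnp()], [run_blockwise_cv()]
#' @export
lnp <- function(stimulus, spikes, method = c("sta", "mle"), bins = NULL,
                whitening = NULL, retention = 1e-7,
                nonlinearity = "auto", n_bins = 25, min_count = 5,
                config = elasticnet_config(), lambda = 1e-2, alpha = 0) {
  method <- match.arg(method)
  fs <- stim_rate(stimulus)
  trains <- as_train_list(spikes)
  nrep <- length(trains)
  stride <- round(fs / 1000)
  all_anchors <- valid_bin_anchors(length(stimulus), fs)
  train_anchors <- if (is.null(bins)) all_anchors
                   else intersect(all_anchors, as.integer(bins) * stride)
  if (!length(train_anchors)) stop("no usable training bins")
  train_bins <- train_anchors / stride

  obj <- list(method = toupper(method), stimulus = stimulus, spikes = trains,
              n_repetitions = nrep, train_bins = train_bins,
              sampling_rate = fs, call = match.call())

  if (method == "sta") {
    fe <- extract_snippets(stimulus)
    if (is.null(whitening)) whitening <- compute_whitening_operator(fe, retention)
    white <- whiten_stimulus(stimulus, whitening)
    ## restrict spikes to the training bins
    keep_bins <- function(tr) {
      b <- spike_bins(tr)
      as.numeric(tr)[b %in% train_bins]
    }
    kept <- lapply(trains, keep_bins)
    filt <- compute_sta(white, kept, sampling_rate = fs)
    ## STE/FE geometry for the nonlinearity, on the whitened stimulus
    sw <- as_samples(white)
    spike_anchors <- unlist(lapply(kept, spike_bins)) * stride
    spike_anchors <- spike_anchors[spike_anchors %in% train_anchors]
    ste <- snippet_matrix(sw, spike_anchors)
    fe_white <- snippet_matrix(sw, train_anchors)
    est <- estimate_nonlinearity(filt, fe_white, ste, n_bins = n_bins,
                                 min_count = min_count)
    est <- fit_nonlinearity(est, kind = nonlinearity)
    obj$filter <- filt
    obj$whitening <- whitening
    obj$nonlinearity <- est
    obj$n_spikes <- attr(filt, "n_spikes_used")
    class(obj) <- c("lnp_sta", "lnp")
  } else {
    gf <- fit_glm_elasticnet(stimulus, trains, config = config,
                             lambda = lambda, alpha = alpha, bins = train_bins)
    obj$filter <- gf$filter
    obj$intercept <- gf$intercept
    obj$nonlinearity <- list(kind = "logistic", intercept = gf$intercept)
    obj$lambda <- gf$lambda
    obj$alpha <- gf$alpha
    obj$cv_table <- gf$cv_table
    obj$n_spikes <- gf$n_spikes
    class(obj) <- c("lnp_mle", "lnp")
  }
  obj
}

#' @export
print.lnp <- function(x, ...) {
  cat(sprintf("Linear-nonlinear-Poisson model (%s fit)\n", x$method))
  cat(sprintf("  filter: 300 taps, -20 ... +10 ms; %d spikes, %d repetitions\n",
              x$n_spikes, x$n_repetitions))
  if (inherits(x, "lnp_sta")) {
    cat(sprintf("  nonlinearity: %s (histogram-ratio fit, RSS %.4g)\n",
                x$nonlinearity$fitted_kind, x$nonlinearity$fit_residual))
    cat(sprintf("  whitening rank: %d\n", attr(x$whitening, "rank")))
  } else {
    cat(sprintf("  logistic link, intercept %.3f; lambda %.4g, alpha %g\n",
                x$intercept, x$lambda, x$alpha))
  }
  invisible(x)
}

#' @export
summary.lnp <- function(object, ...) {
  pl <- peak_latencies(object$filter)
  out <- list(method = object$method, n_spikes = object$n_spikes,
              n_repetitions = object$n_repetitions, peaks = pl,
              filter_norm = sqrt(sum(as.numeric(object$filter)^2)))
  class(out) <- "summary.lnp"
  out
}

#' @export
print.summary.lnp <- function(x, ...) {
  cat(sprintf("LNP model (%s): %d spikes over %d repetitions\n",
              x$method, x$n_spikes, x$n_repetitions))
  cat(sprintf("  filter L2 norm %.4g; shape %s\n", x$filter_norm,
              x$peaks$shape_class))
  cat(sprintf("  negative peak %.1f ms, positive peak %.1f ms\n",
              x$peaks$negative_peak_latency, x$peaks$positive_peak_latency))
  invisible(x)
}

#' @export
coef.lnp <- function(object, ...) {
  taps <- as.numeric(object$filter)
  names(taps) <- sprintf("t%+.1fms", attr(object$filter, "tap_times"))
  if (inherits(object, "lnp_mle")) c(`(Intercept)` = object$intercept, taps)
  else taps
}

#' Predicted firing rate of an LNP model
#'
#' Projects every 1-ms stimulus window onto the filter and applies the
#' model's static nonlinearity (`type = "rate"`) or returns the bare
#' projection (`type = "linear"`, the linear-stage prediction). For STA
#' models the stimulus is whitened with the model's stored operator first,
#' matching the space the filter was estimated in. Bins without a full
#' window are `NA`.
#'
#' @param object a fitted [lnp()] model.
#' @param stimulus a `stimulus_trace`; defaults to the training stimulus.
#' @param type `"rate"` or `"linear"`. Rate units follow the model's
#'   nonlinearity: pooled spikes per 1-ms bin (histogram-ratio scale) for STA
#'   models, per-repetition spike probability per bin for MLE models;
#'   correlation-based scoring is unaffected by the scale.
#' @param ... unused.
#' @return numeric vector with one entry per 1-ms bin of the stimulus.
#' @export
predict.lnp <- function(object, stimulus = NULL, type = c("rate", "linear"),
                        ...) {
  type <- match.arg(type)
  if (is.null(stimulus)) stimulus <- object$stimulus
  fs <- stim_rate(stimulus)
  stride <- round(fs / 1000)
  n_bins_total <- length(stimulus) %/% stride
  anchors <- valid_bin_anchors(length(stimulus), fs)
  s <- if (inherits(object, "lnp_sta")) {
    as_samples(whiten_stimulus(stimulus, object$whitening))
  } else {
    as_samples(stimulus)
  }
  proj <- as.numeric(snippet_matrix(s, anchors) %*% as.numeric(object$filter))
  out <- rep(NA_real_, n_bins_total)
  bin_idx <- anchors / stride + 1L
  if (type == "linear") {
    out[bin_idx] <- proj
    return(out)
  }
  rate <- if (inherits(object, "lnp_sta")) {
    nl <- object$nonlinearity
    ## histogram-ratio units: pooled spikes per 1-ms bin
    pmax(apply_nonlinearity(nl$fitted_kind, proj, nl$params), 0)
  } else {
    stats::plogis(object$intercept + proj)
  }
  out[bin_idx] <- rate
  out
}

#' @export
fitted.lnp <- function(object, ...) {
  ## expected pooled spike count per 1-ms bin
  p <- predict(object)
  if (inherits(object, "lnp_mle")) p * object$n_repetitions else p
}

#' @export
residuals.lnp <- function(object, ...) {
  fs <- object$sampling_rate
  n_bins_total <- length(object$stimulus) %/% round(fs / 1000)
  ## pooled observed counts minus expected pooled counts (response residuals)
  obs <- bin_spike_counts(object$spikes, n_bins_total)
  obs - fitted(object)
}

#' Simulate spike trains from a fitted LNP model
#'
#' Draws one Bernoulli trial per 1-ms bin and repetition with the model's
#' predicted per-repetition spike probability (clamped to \[0, 1\]).
#'
#' @param object a fitted [lnp()] model.
#' @param nsim number of repetitions.
#' @param seed integer seed.
#' @param stimulus optional stimulus (defaults to the training stimulus).
#' @param ... unused.
#' @return list of [spike_train()] objects.
#' @export
simulate.lnp <- function(object, nsim = 1, seed = NULL, stimulus = NULL, ...) {
  if (is.null(stimulus)) stimulus <- object$stimulus
  p <- predict(object, stimulus, type = "rate")
  if (inherits(object, "lnp_sta")) p <- p / object$n_repetitions
  p[is.na(p)] <- 0
  p <- pmin(pmax(p, 0), 1)
  maybe_seed(seed)
  dur <- length(stimulus) / stim_rate(stimulus)
  lapply(seq_len(nsim), function(r) {
    hit <- stats::rbinom(length(p), 1L, p) == 1L
    spike_train((which(hit) - 1L) / 1000, repetition_id = r, duration = dur)
  })
}

#' Plot an LNP model: filter and static nonlinearity
#'
#' @param x a fitted [lnp()] model.
#' @param ... passed to the filter panel's `plot`.
#' @export
plot.lnp <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  tt <- attr(x$filter, "tap_times")
  plot(tt, as.numeric(x$filter), type = "l", xlab = "time to spike [ms]",
       ylab = "filter [AU]", main = sprintf("%s filter", x$method), ...)
  graphics::abline(v = 0, lty = 3)
  if (inherits(x, "lnp_sta")) {
    nl <- x$nonlinearity
    plot(nl$bin_centers[nl$mask], nl$ratio[nl$mask], pch = 16,
         xlab = "filter projection", ylab = "H_STE / H_FE",
         main = sprintf("nonlinearity (%s)", nl$fitted_kind))
    xx <- seq(min(nl$bin_centers), max(nl$bin_centers), length.out = 200)
    graphics::lines(xx, apply_nonlinearity(nl$fitted_kind, xx, nl$params))
  } else {
    xx <- seq(-6, 6, length.out = 200)
    plot(xx, stats::plogis(x$intercept + xx), type = "l",
         xlab = "filter projection", ylab = "spike probability",
         main = "logistic link")
  }
  invisible(x)
}
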