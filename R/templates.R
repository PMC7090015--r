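## Parametric template filters and ground-truth LNP neurons.
##
## The templates are smooth parametric stand-ins for the three filter shapes
## observed in wild-type retina: monophasic negative (cathodic preference),
## monophasic positive (anodic preference) and biphasic (anodic lobe several
## ms before the spike followed by a cathodic lobe near spike time). Default
## peak latencies follow the reported medians: -3.7 ms (monophasic negative),
## -5.5 ms (monophasic positive), and -5.2 / +0.2 ms for the biphasic lobes.

FILTER_CLASSES <- c("monophasic_negative", "monophasic_positive", "biphasic")

#' Construct a linear temporal filter
#'
#' @param taps numeric vector of 300 tap values spanning -20 ... +10 ms
#'   around the spike.
#' @param method estimation method label (`"STA"`, `"MLE"`, or
#'   `"template"`).
#' @param sampling_rate Hz.
#' @return object of class `linear_filter`.
#' @export
linear_filter <- function(taps, method = "template", sampling_rate = 10000) {
  taps <- as.numeric(taps)
  if (length(taps) != FILTER_TAPS) stop("a linear filter has exactly 300 taps")
  if (any(!is.finite(taps))) stop("filter taps must be finite")
  structure(taps, tap_times = filter_tap_times(sampling_rate),
            method = method, class = "linear_filter")
}

#' @export
print.linear_filter <- function(x, ...) {
  tt <- attr(x, "tap_times")
  cat(sprintf("<linear_filter (%s): 300 taps, %.1f ... %.1f ms, peak |amp| %.3g>\n",
              attr(x, "method"), min(tt), max(tt), max(abs(x))))
  invisible(x)
}

#' Parametric template filter
#'
#' Gaussian-lobe construction of the three filter archetypes. Monophasic
#' templates carry a single extremum of the requested sign; the biphasic
#' template is a positive lobe preceding a negative lobe near spike time,
#' with one zero crossing strictly between the lobes.
#'
#' @param filter_class one of `"monophasic_negative"`, `"monophasic_positive"`,
#'   `"biphasic"`.
#' @param peak_latency peak time in ms within (-20, 10); for `biphasic` the
#'   latency of the negative lobe (default +0.2 ms).
#' @param width Gaussian lobe SD in ms (default 2).
#' @param amplitude peak magnitude in arbitrary units (default 1; 0 yields the
#'   all-zero filter).
#' @param secondary_latency for `biphasic`: latency of the positive lobe
#'   (default -5.2 ms).
#' @param secondary_width for `biphasic`: SD of the positive lobe (default 2).
#' @return a [linear_filter()] with attribute `filter_class`.
#' @export
make_template_filter <- function(filter_class = FILTER_CLASSES,
                                 peak_latency = NULL, width = 2, amplitude = 1,
                                 secondary_latency = -5.2, secondary_width = 2) {
  filter_class <- match.arg(filter_class)
  tt <- filter_tap_times()
  check_lat <- function(l) {
    if (l <= min(tt) || l >= max(tt)) stop("peak latency outside the filter window")
  }
  taps <- switch(
    filter_class,
    monophasic_negative = {
      if (is.null(peak_latency)) peak_latency <- -3.7
      check_lat(peak_latency)
      -amplitude * exp(-0.5 * ((tt - peak_latency) / width)^2)
    },
    monophasic_positive = {
      if (is.null(peak_latency)) peak_latency <- -5.5
      check_lat(peak_latency)
      amplitude * exp(-0.5 * ((tt - peak_latency) / width)^2)
    },
    biphasic = {
      if (is.null(peak_latency)) peak_latency <- 0.2
      check_lat(peak_latency); check_lat(secondary_latency)
      if (secondary_latency >= peak_latency)
        stop("biphasic template requires the positive lobe before the negative lobe")
      amplitude * exp(-0.5 * ((tt - secondary_latency) / secondary_width)^2) -
        amplitude * exp(-0.5 * ((tt - peak_latency) / min(width, 1.5))^2)
    })
  f <- linear_filter(taps, method = "template")
  attr(f, "filter_class") <- filter_class
  f
}

## static nonlinearities -------------------------------------------------------

#' Sigmoid and exponential static nonlinearities
#'
#' `nl_sigmoid`: `y_max / (1 + exp(-g (x - x0))) + y_min`.
#' `nl_exponential`: `a * exp(g * x) + y_min`.
#'
#' @param x filter projection values.
#' @param params named list of the respective free parameters.
#' @return numeric vector of (rate-like) outputs.
#' @export
nl_sigmoid <- function(x, params) {
  params$y_max / (1 + exp(-params$g * (x - params$x0))) + params$y_min
}

#' @rdname nl_sigmoid
#' @export
nl_exponential <- function(x, params) {
  params$a * exp(params$g * x) + params$y_min
}

apply_nonlinearity <- function(kind, x, params) {
  switch(kind,
         sigmoid = nl_sigmoid(x, params),
         exponential = nl_exponential(x, params),
         stop("unknown nonlinearity kind: ", kind))
}

#' Ground-truth LNP neuron
#'
#' Bundles a linear filter with a static nonlinearity whose output is used as
#' the per-1-ms-bin Bernoulli spike probability. The filter projection is
#' internally scaled to unit variance over the driving stimulus before the
#' nonlinearity is applied (see [calibrate_neuron()]), so nonlinearity
#' parameters are in projection-SD units.
#'
#' @param filter a [linear_filter()] (or 300-tap numeric vector).
#' @param nonlinearity_kind `"sigmoid"` or `"exponential"`.
#' @param nonlinearity_params named list of parameters; defaults to a sigmoid
#'   with `y_min = 0`, `y_max = 0.25`, `g = 2` and an uncalibrated threshold.
#' @param filter_class archetype label (taken from the filter when present).
#' @param target_rate desired mean firing rate in spikes/s (default 40).
#' @return object of class `lnp_neuron`.
#' @export
lnp_neuron <- function(filter, nonlinearity_kind = c("sigmoid", "exponential"),
                       nonlinearity_params = NULL, filter_class = NULL,
                       target_rate = 40) {
  nonlinearity_kind <- match.arg(nonlinearity_kind)
  if (!inherits(filter, "linear_filter")) filter <- linear_filter(filter)
  if (is.null(nonlinearity_params)) {
    nonlinearity_params <- if (nonlinearity_kind == "sigmoid") {
      list(y_min = 0, y_max = 0.25, g = 2, x0 = NA_real_)
    } else {
      list(a = NA_real_, g = 1, y_min = 0)
    }
  }
  if (is.null(filter_class)) filter_class <- attr(filter, "filter_class")
  structure(list(filter = filter, nonlinearity_kind = nonlinearity_kind,
                 nonlinearity_params = nonlinearity_params,
                 filter_class = filter_class, target_rate = target_rate,
                 projection_sd = NA_real_),
            class = "lnp_neuron")
}

#' @export
print.lnp_neuron <- function(x, ...) {
  cat(sprintf("<lnp_neuron: %s filter, %s nonlinearity, target %g Hz%s>\n",
              if (is.null(x$filter_class)) "custom" else x$filter_class,
              x$nonlinearity_kind, x$target_rate,
              if (is.na(x$projection_sd)) " (uncalibrated)" else ""))
  invisible(x)
}

#' Calibrate a ground-truth neuron to its target rate on a stimulus
#'
#' Records the SD of the filter projection over the stimulus snippet ensemble
#' and solves (deterministically, by root finding) for the free offset of the
#' nonlinearity — the sigmoid threshold `x0` or the exponential scale `a` —
#' so the mean Bernoulli probability equals `target_rate` per 1-ms bin.
#'
#' @param neuron an [lnp_neuron()].
#' @param stimulus the driving `stimulus_trace`.
#' @return the calibrated neuron.
#' @export
calibrate_neuron <- function(neuron, stimulus) {
  an <- valid_bin_anchors(length(stimulus), stim_rate(stimulus))
  X <- snippet_matrix(as_samples(stimulus), an)
  z <- as.numeric(X %*% as.numeric(neuron$filter))
  psd <- stats::sd(z)
  if (psd == 0) psd <- 1   # zero filter: projection identically zero
  zs <- z / psd
  target_p <- neuron$target_rate / 1000
  p <- neuron$nonlinearity_params
  if (neuron$nonlinearity_kind == "sigmoid") {
    fobj <- function(x0) mean(nl_sigmoid(zs, modifyList(p, list(x0 = x0)))) - target_p
    if (target_p <= p$y_min || target_p >= p$y_min + p$y_max)
      stop("target rate unreachable with the given sigmoid bounds")
    p$x0 <- stats::uniroot(fobj, c(-50, 50), tol = 1e-10)$root
  } else {
    # a * mean(exp(g z)) + y_min = target
    m <- mean(exp(p$g * zs))
    p$a <- (target_p - p$y_min) / m
  }
  neuron$nonlinearity_params <- p
  neuron$projection_sd <- psd
  neuron
}
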