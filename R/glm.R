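## Maximum-likelihood filter estimation: elastic-net-penalized Bernoulli
## regression of 1-ms spike labels on raw stimulus snippets.
##
## The loss is the average Bernoulli negative log-likelihood over time bins
## plus the elastic-net penalty
##   J(b0, b) = -(1/N) sum_t [y log mu + (1 - y) log(1 - mu)]
##              + lambda [ (1 - alpha)/2 sum b^2 + alpha sum |b| ]
## with mu = plogis(b0 + X b) and N the number of (bin x repetition) rows.
## The intercept is never penalized. Optimization is delegated to glmnet
## (repetitions collapsed to binomial counts); the loss and gradient here are
## the package's own reference implementation used for verification.

#' Elastic-net hyperparameter grids
#'
#' @param lambda_grid penalty strengths (default 5 log-spaced values in
#'   \[1e-4, 1e-2\]).
#' @param alpha_grid L1 mixing fractions (default `c(0, 0.01, 0.1, 0.5, 1)`).
#' @param cv_folds number of contiguous cross-validation blocks (default 5).
#' @return list of class `elasticnet_config`.
#' @export
elasticnet_config <- function(lambda_grid = 10^seq(-4, -2, length.out = 5),
                              alpha_grid = c(0, 0.01, 0.1, 0.5, 1),
                              cv_folds = 5) {
  if (any(lambda_grid <= 0)) stop("all lambda values must be positive")
  if (any(alpha_grid < 0 | alpha_grid > 1)) stop("alpha values must lie in [0, 1]")
  structure(list(lambda_grid = sort(lambda_grid, decreasing = TRUE),
                 alpha_grid = alpha_grid, cv_folds = cv_folds),
            class = "elasticnet_config")
}

#' Penalized Bernoulli loss and gradient
#'
#' Reference implementation of the training objective; `enet_gradient`
#' returns the exact gradient with respect to `(b0, b)` (for `alpha > 0` the
#' subgradient `sign(b)` is used at nonzero coordinates).
#'
#' @param b0 intercept.
#' @param b coefficient vector.
#' @param X design matrix (rows = bins, columns = stimulus lags).
#' @param y 0/1 labels.
#' @param lambda,alpha elastic-net hyperparameters.
#' @return scalar loss / gradient vector of length `length(b) + 1`
#'   (intercept first).
#' @export
enet_loss <- function(b0, b, X, y, lambda, alpha) {
  eta <- b0 + as.numeric(X %*% b)
  ## numerically stable -[y log mu + (1-y) log(1-mu)] = log(1+exp(eta)) - y eta
  nll <- mean(ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta))) - y * eta)
  nll + lambda * ((1 - alpha) / 2 * sum(b^2) + alpha * sum(abs(b)))
}

#' @rdname enet_loss
#' @export
enet_gradient <- function(b0, b, X, y, lambda, alpha) {
  eta <- b0 + as.numeric(X %*% b)
  mu <- stats::plogis(eta)
  r <- mu - y
  g0 <- mean(r)
  gb <- as.numeric(crossprod(X, r)) / length(y) +
    lambda * ((1 - alpha) * b + alpha * sign(b))
  c(g0, gb)
}

## Build the design for a set of 0-based bin anchors and pooled labels per
## repetition. Returns binomial counts (one row per bin) plus per-rep labels.
glm_design <- function(stimulus, trains, anchors, sampling_rate) {
  s <- as_samples(stimulus)
  X <- snippet_matrix(s, anchors)
  stride <- round(sampling_rate / 1000)
  bins <- anchors / stride
  nrep <- length(trains)
  succ <- integer(length(bins))
  for (tr in trains) {
    b <- spike_bins(tr)
    hit <- bins %in% b          # label clipping: >=1 spike in bin -> 1
    succ <- succ + as.integer(hit)
  }
  list(X = X, succ = succ, nrep = nrep, bins = bins)
}

glmnet_fit_one <- function(X, succ, nrep, lambda_seq, alpha) {
  ## glmnet normalizes the binomial-counts likelihood by the number of rows,
  ## while the package loss averages over bin x repetition; rescale lambda.
  glmnet::glmnet(X, cbind(nrep - succ, succ), family = "binomial",
                 alpha = alpha, lambda = lambda_seq * nrep,
                 standardize = TRUE, thresh = 1e-9)
}

#' Fit the LNP filter by penalized maximum likelihood
#'
#' Regresses binary 1-ms spike labels on the raw (not whitened) stimulus
#' snippets with a logit link and elastic-net penalty. Hyperparameters are
#' either fixed (`lambda`/`alpha` scalars) or selected by a grid search over
#' `config` using contiguous-block cross-validation (blocks respect the
#' temporal ordering of the recording); the selected pair minimizes the mean
#' validation negative log-likelihood, with ties and near-ties (within one
#' standard error) resolved toward the strongest penalty.
#'
#' @param stimulus the raw `stimulus_trace`.
#' @param spikes a [spike_train()] or list of repetitions.
#' @param config an [elasticnet_config()].
#' @param lambda,alpha optional fixed hyperparameters bypassing the search.
#' @param bins optional 0-based bin indices to train on (defaults to all bins
#'   with a full stimulus window).
#' @return list of class `glm_fit`: `filter` (a [linear_filter()], method
#'   `"MLE"`), `intercept`, `lambda`, `alpha`, `cv_table` (when searched) and
#'   bookkeeping.
#' @export
fit_glm_elasticnet <- function(stimulus, spikes, config = elasticnet_config(),
                               lambda = NULL, alpha = NULL, bins = NULL) {
  fs <- stim_rate(stimulus)
  trains <- as_train_list(spikes)
  stride <- round(fs / 1000)
  anchors <- valid_bin_anchors(length(stimulus), fs)
  if (!is.null(bins)) anchors <- intersect(anchors, as.integer(bins) * stride)
  if (length(anchors) < 2 * FILTER_TAPS)
    warning("fewer training bins than twice the filter dimension")
  d <- glm_design(stimulus, trains, anchors, fs)
  if (all(d$succ == 0) || all(d$succ == d$nrep))
    stop("degenerate labels: all bins silent or all bins spiking")
  cv_table <- NULL
  if (is.null(lambda) || is.null(alpha)) {
    sel <- cv_grid_search(d, config)
    lambda <- sel$lambda; alpha <- sel$alpha; cv_table <- sel$table
  }
  fit <- glmnet_fit_one(d$X, d$succ, d$nrep, lambda, alpha)
  beta <- as.numeric(fit$beta[, 1])
  b0 <- as.numeric(fit$a0[1])
  f <- linear_filter(beta, method = "MLE", sampling_rate = fs)
  structure(list(filter = f, intercept = b0, lambda = lambda, alpha = alpha,
                 cv_table = cv_table, n_bins = length(d$bins),
                 n_spikes = sum(d$succ), n_repetitions = d$nrep),
            class = "glm_fit")
}

## contiguous-block CV over the (lambda, alpha) grid
cv_grid_search <- function(d, config) {
  nb <- length(d$bins)
  folds <- cut(seq_len(nb), breaks = config$cv_folds, labels = FALSE)
  lam <- config$lambda_grid
  al <- config$alpha_grid
  mean_nll <- matrix(NA_real_, length(al), length(lam),
                     dimnames = list(alpha = al, lambda = signif(lam, 3)))
  se_nll <- mean_nll
  for (ai in seq_along(al)) {
    fold_nll <- matrix(NA_real_, config$cv_folds, length(lam))
    for (k in seq_len(config$cv_folds)) {
      trn <- folds != k
      if (all(d$succ[trn] == 0)) next
      fit <- glmnet_fit_one(d$X[trn, , drop = FALSE], d$succ[trn], d$nrep,
                            lam, al[ai])
      coefs <- rbind(fit$a0, as.matrix(fit$beta))
      eta <- cbind(1, d$X[!trn, , drop = FALSE]) %*% coefs
      ## validation NLL per bin-x-rep trial
      s <- d$succ[!trn]; f <- d$nrep - s
      nllm <- -(s * stats::plogis(eta, log.p = TRUE) +
                  f * stats::plogis(-eta, log.p = TRUE))
      got <- match(signif(lam, 10), signif(fit$lambda / d$nrep, 10))
      for (li in seq_along(lam)) {
        if (!is.na(got[li]))
          fold_nll[k, li] <- sum(nllm[, got[li]]) / (length(s) * d$nrep)
      }
    }
    mean_nll[ai, ] <- colMeans(fold_nll, na.rm = TRUE)
    se_nll[ai, ] <- apply(fold_nll, 2, stats::sd, na.rm = TRUE) /
      sqrt(config$cv_folds)
  }
  best <- which(mean_nll == min(mean_nll, na.rm = TRUE), arr.ind = TRUE)[1, ]
  ## one-SE rule along lambda at the winning alpha (lambda sorted decreasing,
  ## so the first index within one SE is the strongest penalty)
  thr <- mean_nll[best[1], best[2]] + se_nll[best[1], best[2]]
  li <- which(mean_nll[best[1], ] <= thr)[1]
  list(lambda = lam[li], alpha = al[best[1]],
       table = list(mean = mean_nll, se = se_nll))
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("<glm_fit: 300-tap MLE filter, lambda %.4g, alpha %g, %d spikes / %d bins x %d reps>\n",
              x$lambda, x$alpha, x$n_spikes, x$n_bins, x$n_repetitions))
  invisible(x)
}
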