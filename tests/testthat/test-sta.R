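test_that("the STA equals a scalar double-loop oracle exactly", {
  set.seed(41)
  s <- rnorm(6000)
  times <- sort(sample(2100:5800, 25)) / 10000   # spike times in s
  sta <- compute_sta(s, spike_train(times), sampling_rate = 10000)
  # oracle: explicit loop over spikes and taps
  oracle <- numeric(300)
  bins <- floor(times * 1000)
  for (tau in 1:300) {
    acc <- 0
    for (b in bins) acc <- acc + s[b * 10 + (tau - 201) + 1]
    oracle[tau] <- acc / length(bins)
  }
  expect_lt(max(abs(as.numeric(sta) - oracle)), 1e-12)
})

test_that("a single spike returns its own stimulus window exactly", {
  set.seed(42)
  s <- rnorm(5000)
  sta <- compute_sta(s, spike_train(0.25), sampling_rate = 10000)
  expect_equal(as.numeric(sta), s[(2500 - 200 + 1):(2500 + 100)])
  expect_equal(attr(sta, "n_spikes_used"), 1L)
  # windows leaving the trace are skipped and counted
  sta2 <- compute_sta(s, spike_train(c(0.001, 0.25)), sampling_rate = 10000)
  expect_equal(attr(sta2, "n_spikes_skipped"), 1L)
  expect_error(compute_sta(s, spike_train(0.001), sampling_rate = 10000),
               "usable")
})

test_that("spiking at every bin averages white noise to near zero", {
  set.seed(43)
  s <- rnorm(50000)
  times <- (200:4969) / 1000
  sta <- compute_sta(s, spike_train(times), sampling_rate = 10000)
  n <- length(times)
  expect_true(all(abs(as.numeric(sta)) < 3 / sqrt(n) * 1.5))
})

test_that("identical STE and FE give a constant unit ratio", {
  set.seed(44)
  fe <- matrix(rnorm(2000 * 50), ncol = 50)
  filt <- rnorm(50)
  est <- estimate_nonlinearity(filt, fe, fe, n_bins = 20)
  expect_true(all(est$ratio[est$mask] == 1))
})

test_that("an STE drawn from the top projection decile produces a threshold-shaped ratio", {
  set.seed(45)
  fe <- matrix(rnorm(5000 * 30), ncol = 30)
  filt <- rnorm(30)
  proj <- as.numeric(fe %*% filt)
  ste <- fe[proj >= stats::quantile(proj, 0.9), ]
  est <- estimate_nonlinearity(filt, fe, ste, n_bins = 20)
  usable <- which(est$mask)
  lower <- usable[est$bin_centers[usable] < stats::quantile(proj, 0.8)]
  upper <- usable[est$bin_centers[usable] > stats::quantile(proj, 0.92)]
  expect_true(all(est$ratio[lower] == 0))
  expect_true(all(est$ratio[upper] > 0))
  expect_error(estimate_nonlinearity(filt, fe, fe[0, ]), "empty")
})

test_that("the estimated ratio tracks the generating nonlinearity on simulated data", {
  m <- fx_models()$sta
  nl <- m$nonlinearity
  cell <- fx_cell()
  truth_par <- cell$neuron$nonlinearity_params
  # rank correlation against the true sigmoid over the usable bin centers;
  # centers are only defined up to the projection scale, which a rank
  # correlation ignores
  x <- nl$bin_centers[nl$mask]
  r <- nl$ratio[nl$mask]
  expect_gt(stats::cor(r, nl_sigmoid(scale(x), truth_par),
                       method = "spearman"), 0.9)
})

test_that("parametric nonlinearity fits recover noiseless parameters within 1%", {
  x <- seq(-3, 3, length.out = 25)
  truth <- list(y_max = 1, g = 2, x0 = 0, y_min = 0)
  est <- list(bin_centers = x, ratio = nl_sigmoid(x, truth),
              mask = rep(TRUE, 25))
  class(est) <- "nonlinearity_estimate"
  fit <- fit_nonlinearity(est, kind = "sigmoid")
  expect_equal(fit$params$y_max, 1, tolerance = 0.01)
  expect_equal(fit$params$g, 2, tolerance = 0.01)
  expect_equal(fit$params$x0, 0, tolerance = 0.01)
  expect_lt(fit$fit_residual, 1e-10)
  # exponential self-consistency
  truth_e <- list(a = 0.5, g = 1.2, y_min = 0.1)
  est_e <- est
  est_e$ratio <- nl_exponential(x, truth_e)
  fit_e <- fit_nonlinearity(est_e, kind = "exponential")
  expect_equal(fit_e$params$a, 0.5, tolerance = 0.01)
  expect_equal(fit_e$params$g, 1.2, tolerance = 0.01)
})

test_that("a constant ratio degenerates gracefully to a flat fit", {
  x <- seq(-2, 2, length.out = 25)
  est <- list(bin_centers = x, ratio = rep(0.3, 25), mask = rep(TRUE, 25))
  class(est) <- "nonlinearity_estimate"
  fit <- fit_nonlinearity(est, kind = "sigmoid")
  expect_lt(fit$fit_residual, 1e-8)
  pred <- nl_sigmoid(x, fit$params)
  expect_equal(pred, rep(0.3, 25), tolerance = 1e-3)
})

test_that("the sigmoid threshold is recovered under noise across seeds", {
  x <- seq(-3, 3, length.out = 25)
  truth <- list(y_max = 1, g = 2, x0 = 0.4, y_min = 0)
  errs <- vapply(1:50, function(s) {
    set.seed(600 + s)
    est <- list(bin_centers = x,
                ratio = nl_sigmoid(x, truth) + rnorm(25, sd = 0.05),
                mask = rep(TRUE, 25))
    class(est) <- "nonlinearity_estimate"
    fit <- fit_nonlinearity(est, kind = "sigmoid")
    abs(fit$params$x0 - truth$x0)
  }, 0)
  expect_true(mean(errs < 0.2 * sd(x)) >= 0.95)
})
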