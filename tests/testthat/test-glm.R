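test_that("the loss gradient matches central finite differences", {
  set.seed(51)
  X <- matrix(rnorm(80 * 12), ncol = 12)
  y <- rbinom(80, 1, 0.3)
  b0 <- 0.2; b <- rnorm(12, sd = 0.5)
  for (al in c(0, 1)) {
    g <- enet_gradient(b0, b, X, y, lambda = 1e-3, alpha = al)
    h <- 1e-6
    num <- vapply(0:12, function(j) {
      bump <- function(d) {
        if (j == 0) enet_loss(b0 + d, b, X, y, 1e-3, al)
        else { bb <- b; bb[j] <- bb[j] + d; enet_loss(b0, bb, X, y, 1e-3, al) }
      }
      (bump(h) - bump(-h)) / (2 * h)
    }, 0)
    expect_lt(max(abs(g - num) / pmax(abs(num), 1e-8)), 1e-5)
  }
})

test_that("a constant-rate cell reduces to an intercept-only model", {
  gen <- fixture("short_stim", function()
    generate_stimulus(stimulus_config(duration = 1, seed = 55)))
  neuron <- lnp_neuron(linear_filter(rep(0, 300)),
                       nonlinearity_params = list(y_min = 0.3, y_max = 0,
                                                  g = 1, x0 = 0))
  neuron$projection_sd <- 1
  trains <- simulate_lnp_spikes(neuron, gen$stimulus, n_repetitions = 5,
                                seed = 52)
  fit <- fit_glm_elasticnet(gen$stimulus, trains, lambda = 1e-2, alpha = 1)
  expect_equal(fit$intercept, stats::qlogis(0.3), tolerance = 0.1)
  expect_lt(sqrt(sum(as.numeric(fit$filter)^2)), 0.05)
})

test_that("training likelihood degrades monotonically with the penalty strength", {
  gen <- fixture("short_stim", function()
    generate_stimulus(stimulus_config(duration = 1, seed = 55)))
  cell <- fixture("short_cell", function() {
    neuron <- lnp_neuron(make_template_filter("monophasic_negative"))
    simulate_lnp_spikes(neuron, gen$stimulus, seed = 53)
  })
  lams <- 10^seq(-4, -2, length.out = 5)
  anchors <- erflnp:::valid_bin_anchors(length(gen$stimulus))
  X <- erflnp:::snippet_matrix(as.numeric(gen$stimulus), anchors)
  bins <- anchors / 10
  nll <- vapply(lams, function(lam) {
    fit <- fit_glm_elasticnet(gen$stimulus, cell, lambda = lam, alpha = 0.5)
    b <- as.numeric(fit$filter)
    labels <- unlist(lapply(cell, function(tr) as.integer(bins %in% spike_bins(tr))))
    Xs <- X[rep(seq_len(nrow(X)), length(cell)), ]
    enet_loss(fit$intercept, b, Xs, labels, lambda = 0, alpha = 0)
  }, 0)
  expect_true(all(diff(nll) >= -1e-10))
})

test_that("the average-likelihood normalization makes the loss sample-size stable", {
  set.seed(54)
  X <- matrix(rnorm(200 * 10), ncol = 10)
  y <- rbinom(200, 1, 0.2)
  b0 <- -1; b <- rnorm(10, sd = 0.3)
  l1 <- enet_loss(b0, b, X, y, 1e-3, 0.5)
  l2 <- enet_loss(b0, b, rbind(X, X), c(y, y), 1e-3, 0.5)
  expect_lt(abs(l2 - l1) / abs(l1), 0.02)
})

test_that("the glmnet solution attains a loss no worse than perturbed candidates", {
  gen <- fixture("short_stim", function()
    generate_stimulus(stimulus_config(duration = 1, seed = 55)))
  cell <- fixture("short_cell", function() {
    neuron <- lnp_neuron(make_template_filter("monophasic_negative"))
    simulate_lnp_spikes(neuron, gen$stimulus, seed = 53)
  })
  fit <- fit_glm_elasticnet(gen$stimulus, cell, lambda = 1e-3, alpha = 0.5)
  anchors <- erflnp:::valid_bin_anchors(length(gen$stimulus))
  X <- erflnp:::snippet_matrix(as.numeric(gen$stimulus), anchors)
  bins <- anchors / 10
  labels <- unlist(lapply(cell, function(tr) as.integer(bins %in% spike_bins(tr))))
  Xs <- X[rep(seq_len(nrow(X)), length(cell)), ]
  b <- as.numeric(fit$filter)
  l_opt <- enet_loss(fit$intercept, b, Xs, labels, 1e-3, 0.5)
  set.seed(55)
  for (i in 1:10) {
    l_pert <- enet_loss(fit$intercept + rnorm(1, sd = 0.02),
                        b + rnorm(300, sd = 0.002), Xs, labels, 1e-3, 0.5)
    expect_gte(l_pert, l_opt - 1e-7)
  }
})

test_that("cross-validated grid search returns grid members and a search table", {
  gen <- fixture("short_stim", function()
    generate_stimulus(stimulus_config(duration = 1, seed = 55)))
  cell <- fixture("short_cell", function() {
    neuron <- lnp_neuron(make_template_filter("monophasic_negative"))
    simulate_lnp_spikes(neuron, gen$stimulus, seed = 53)
  })
  cfg <- elasticnet_config(alpha_grid = c(0, 0.5))
  fit <- fit_glm_elasticnet(gen$stimulus, cell, config = cfg,
                            lambda = NULL, alpha = NULL)
  expect_true(fit$lambda %in% cfg$lambda_grid)
  expect_true(fit$alpha %in% cfg$alpha_grid)
  expect_equal(dim(fit$cv_table$mean), c(2, 5))
  expect_true(all(is.finite(fit$cv_table$mean)))
})

test_that("degenerate labels are rejected", {
  gen <- fixture("short_stim", function()
    generate_stimulus(stimulus_config(duration = 1, seed = 55)))
  empty <- spike_train(numeric(0), duration = 1)
  expect_error(fit_glm_elasticnet(gen$stimulus, empty, lambda = 1e-3, alpha = 0),
               "degenerate")
})
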