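test_that("identical repetitions give a reliability index of exactly 1", {
  base <- spike_train(c(0.1, 0.5, 0.55, 2.2, 4.0), duration = 5)
  trials <- lapply(1:5, function(r) spike_train(as.numeric(base),
                                                repetition_id = r, duration = 5))
  res <- reliability_index(trials)
  expect_equal(res$ri, 1)
  expect_false(res$degenerate)
  expect_error(reliability_index(trials[1]), "2 repetitions")
})

test_that("independent Poisson repetitions give a reliability index near zero", {
  set.seed(31)
  ris <- vapply(1:200, function(s) {
    trials <- lapply(1:5, function(r) poisson_train(20, 5, r))
    reliability_index(trials)$ri
  }, 0)
  expect_lt(abs(mean(ris, na.rm = TRUE)), 0.05)
})

test_that("an empty repetition flags degenerate variance and yields NaN", {
  trials <- c(lapply(1:4, function(r) spike_train(c(0.1, 0.2, 3), r, duration = 5)),
              list(spike_train(numeric(0), 5L, duration = 5)))
  res <- reliability_index(trials)
  expect_true(res$degenerate)
  expect_true(is.nan(res$ri))
  expect_warning(ok <- classify_reliable(res), "NaN")
  expect_false(ok)
})

test_that("reliability is invariant under relabeling repetitions", {
  set.seed(8)
  trials <- lapply(1:5, function(r) poisson_train(30, 5, r))
  r1 <- reliability_index(trials)$ri
  r2 <- reliability_index(trials[c(3, 1, 5, 2, 4)])$ri
  expect_identical(r1, r2)
})

test_that("reliability increases with common rate-modulation depth", {
  depths <- c(0, 0.25, 0.5, 0.75, 1)
  set.seed(77)
  mean_ri <- vapply(depths, function(d) {
    mean(vapply(1:50, function(s) {
      tgrid <- seq(0, 5, by = 0.002)[-1]
      lam <- 20 * (1 + d * sin(2 * pi * 3 * tgrid))
      trials <- lapply(1:5, function(r) {
        counts <- stats::rpois(length(lam), lam * 0.002)
        spike_train(sort(rep(tgrid - 0.002, counts) +
                           stats::runif(sum(counts), 0, 0.002)),
                    r, duration = 5)
      })
      reliability_index(trials)$ri
    }, 0), na.rm = TRUE)
  }, 0)
  expect_gt(stats::cor(depths, mean_ri, method = "spearman"), 0.9)
})

test_that("reliability classification uses a strict threshold", {
  expect_true(classify_reliable(0.16))
  expect_false(classify_reliable(0.15))
})

test_that("bias index follows the ON/OFF spike counts and thresholds", {
  on_only <- generate_light_responses("ON", transiency = 0.3, seed = 1)
  b <- bias_index(on_only)
  expect_equal(b$bias_index, 1)
  expect_identical(b$polarity_class, "ON")
  off_only <- generate_light_responses("OFF", transiency = 0.3, seed = 1)
  b2 <- bias_index(off_only)
  expect_equal(b2$bias_index, -1)
  expect_identical(b2$polarity_class, "OFF")
  # hand case: R_ON = 30, R_OFF = 50 -> BI = -0.25, boundary-inclusive ON-OFF
  trial <- spike_train(sort(c(seq(0.0, 0.29, length.out = 30),
                              seq(0.5, 0.79, length.out = 50))), duration = 1)
  b3 <- bias_index(list(trial))
  expect_equal(b3$bias_index, -0.25)
  expect_identical(b3$polarity_class, "ON-OFF")
  # empty response -> undefined
  b4 <- bias_index(list(spike_train(numeric(0), duration = 1)))
  expect_true(b4$undefined)
})

test_that("bias index is antisymmetric under swapping the ON and OFF windows", {
  tr <- generate_light_responses("ON-OFF", transiency = 0.2, n_trials = 4, seed = 6)
  b <- bias_index(tr, onset_times = 0, offset_times = 0.5)
  bs <- bias_index(tr, onset_times = 0.5, offset_times = 0)
  expect_identical(b$bias_index, -bs$bias_index)
})

test_that("transiency index matches hand-computed histograms", {
  # all spikes in the first bin -> 1 - 1/10
  t1 <- transiency_index(trains_from_histogram(c(12, rep(0, 9))), 0)
  expect_equal(t1$transiency_index, 0.9)
  # uniform histogram -> 0
  t2 <- transiency_index(trains_from_histogram(rep(5, 10)), 0)
  expect_equal(t2$transiency_index, 0)
  # [10, 5 x 9]: normalized mean (1 + 9 * 0.5) / 10 -> TI = 0.45
  t3 <- transiency_index(trains_from_histogram(c(10, rep(5, 9))), 0)
  expect_equal(t3$transiency_index, 0.45)
})

test_that("transiency is invariant under uniform scaling of spike counts", {
  h <- c(8, 3, 5, 1, 2, 2, 4, 0, 1, 6)
  a <- transiency_index(trains_from_histogram(h), 0)$transiency_index
  b <- transiency_index(trains_from_histogram(3 * h), 0)$transiency_index
  expect_equal(a, b)
})

test_that("ON-OFF transiency averages the two phases and profiles classify correctly", {
  tr <- generate_light_responses("ON-OFF", transiency = 0.5, n_trials = 50, seed = 10)
  m <- light_response_metrics(tr)
  expect_identical(m$polarity_class, "ON-OFF")
  expect_equal(m$transiency_index, mean(m$per_phase))
  expect_length(m$per_phase, 2)
})
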