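test_that("Bessel band-pass passes the spike band and rejects the stimulus band", {
  fs <- 20000
  t <- seq(0, 1, by = 1 / fs)[-1]
  cfg <- bandpass_config()      # 1000-9500 Hz
  # zero in, zero out
  expect_equal(bandpass_filter(rep(0, fs), cfg, sampling_rate = fs),
               rep(0, fs))
  rms_tail <- function(x) sqrt(mean(x[(fs / 2):fs]^2))
  s100 <- sin(2 * pi * 100 * t)
  out100 <- bandpass_filter(s100, cfg, sampling_rate = fs)
  expect_lt(rms_tail(out100), 0.1 * rms_tail(s100))
  s3k <- sin(2 * pi * 3000 * t)
  out3k <- bandpass_filter(s3k, cfg, sampling_rate = fs)
  expect_gt(rms_tail(out3k), 0.7 * rms_tail(s3k))
  expect_error(bandpass_filter(s100, cfg, sampling_rate = 10000), "Nyquist")
  expect_error(bandpass_config(low = 2000, high = 1000), "low")
})

test_that("artefact factor is the least-squares projection coefficient", {
  gen <- fx_stimulus()
  s <- as.numeric(gen$stimulus)
  expect_equal(estimate_artefact_factor(2 * s, s), 2)
  # orthogonal component projects to zero
  w <- rnorm(length(s))
  w_orth <- w - sum(w * s) / sum(s * s) * s
  expect_equal(estimate_artefact_factor(w_orth, s), 0, tolerance = 1e-12)
  # least-squares consistency in white noise
  set.seed(9)
  r <- 1.37 * s + rnorm(length(s))
  expect_equal(estimate_artefact_factor(r, s), 1.37, tolerance = 0.01)
  expect_error(estimate_artefact_factor(s, rep(0, length(s))), "zero")
  expect_error(estimate_artefact_factor(s[1:10], s), "length")
})

test_that("factor estimation is linear and minimizes the residual over a dense grid", {
  gen <- fx_stimulus()
  s <- as.numeric(gen$stimulus)[1:5000]
  set.seed(4)
  r1 <- rnorm(5000); r2 <- rnorm(5000)
  f1 <- estimate_artefact_factor(r1, s); f2 <- estimate_artefact_factor(r2, s)
  expect_equal(estimate_artefact_factor(3 * r1 - 0.5 * r2, s),
               3 * f1 - 0.5 * f2, tolerance = 1e-12)
  r <- 0.8 * s + rnorm(5000)
  fhat <- estimate_artefact_factor(r, s)
  grid <- seq(fhat - 0.2, fhat + 0.2, length.out = 2001)
  rss <- vapply(grid, function(f) sum((r - f * s)^2), 0)
  expect_equal(grid[which.min(rss)], fhat, tolerance = 2e-4)
})

test_that("subtracting the scaled stimulus leaves an orthogonal residual", {
  gen <- fx_stimulus()
  s <- as.numeric(gen$stimulus)
  expect_equal(subtract_artefact(5 * s, s, 5), rep(0, length(s)),
               ignore_attr = TRUE)
  r <- s + rnorm(length(s))
  expect_equal(as.numeric(subtract_artefact(r, s, 0)), r)
  res <- subtract_artefact(r, s)
  expect_lt(abs(sum(as.numeric(res) * s)),
            1e-8 * sqrt(sum(r^2)) * sqrt(sum(s^2)))
})

test_that("the chain recovers the artefact scale and suppresses stimulus-band power", {
  gen <- fx_stimulus()
  cell <- fx_cell()
  tr <- cell$trains[[1]]
  raw <- synthesize_raw_recording(gen$stimulus, tr, artefact_gain = 100, seed = 21)
  pp <- preprocess_raw(raw, gen$stimulus)
  expect_equal(pp$factor, 100, tolerance = 0.01 * 100)
  band_power <- function(x) {
    sp <- stats::spec.pgram(stats::ts(as.numeric(x), frequency = 10000),
                            plot = FALSE, taper = 0.1)
    mean(sp$spec[sp$freq >= 10 & sp$freq <= 100])
  }
  drop_db <- 10 * log10(band_power(raw) / band_power(pp$clean))
  expect_gte(drop_db, 20)
})

test_that("artefact subtraction barely touches spike energy (matched-filter peak)", {
  gen <- fx_stimulus()
  times <- seq(0.5, 4.5, by = 0.05)
  spk <- spike_train(times, duration = 5)
  raw <- synthesize_raw_recording(gen$stimulus, spk, artefact_gain = 100,
                                  noise_sd = 0)
  ref <- synthesize_raw_recording(gen$stimulus, spk, artefact_gain = 0,
                                  noise_sd = 0)
  cfg <- bandpass_config(high = 4750)
  tpl_bp <- as.numeric(bandpass_filter(c(spike_template(), rep(0, 20)), cfg,
                                       sampling_rate = 10000))
  mfpeak <- function(x) {
    xc <- stats::filter(as.numeric(x), rev(tpl_bp), sides = 1)
    max(abs(xc), na.rm = TRUE)
  }
  clean <- preprocess_raw(raw, gen$stimulus)$clean
  ref_bp <- bandpass_filter(ref, cfg)
  expect_gt(mfpeak(clean), 0.85 * mfpeak(ref_bp))   # <= 15% loss
  expect_equal(mfpeak(clean), mfpeak(ref_bp), tolerance = 0.1)
})

test_that("threshold detection finds inserted spikes and nothing else", {
  expect_length(detect_spikes_threshold(rep(0, 1000)), 0)
  # one noiseless template -> exactly one detection within 0.5 ms
  x <- numeric(10000)
  x[5001:5010] <- spike_template()
  det <- detect_spikes_threshold(x, sampling_rate = 10000)
  expect_length(det, 1)
  expect_lt(abs(as.numeric(det) - 0.5), 5e-4 + 1e-9)
  # full synthetic chain: sensitivity >= 0.9, precision >= 0.95
  gen <- fx_stimulus()
  cell <- fx_cell()
  tr <- cell$trains[[1]]
  raw <- synthesize_raw_recording(gen$stimulus, tr, seed = 77)
  pp <- preprocess_raw(raw, gen$stimulus, detect = TRUE)
  m <- match_spike_times(as.numeric(pp$spikes), as.numeric(tr))
  expect_gte(m["sensitivity"], 0.9)
  expect_gte(m["precision"], 0.95)
})
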