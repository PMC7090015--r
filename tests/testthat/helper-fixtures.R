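# Shared fixtures, computed lazily and cached for the whole run.
# Everything is generated in code from fixed seeds; nothing is stored on disk.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# default 5 s stimulus (50 000 samples), seed 101
fx_stimulus <- function() {
  fixture("stimulus", function() generate_stimulus(stimulus_config(seed = 101)))
}

# whitening operator + whitened trace for the default stimulus
fx_whitening <- function() {
  fixture("whitening", function() {
    gen <- fx_stimulus()
    W <- compute_whitening_operator(extract_snippets(gen$stimulus))
    list(W = W, white = whiten_stimulus(gen$stimulus, W))
  })
}

# one simulated biphasic cell on the default stimulus (5 reps, ~40 Hz)
fx_cell <- function() {
  fixture("cell", function() {
    gen <- fx_stimulus()
    neuron <- lnp_neuron(make_template_filter("biphasic"))
    trains <- simulate_lnp_spikes(neuron, gen$stimulus, seed = 202)
    list(trains = trains, neuron = attr(trains, "neuron"),
         truth = as.numeric(attr(trains, "neuron")$filter))
  })
}

# fitted STA and MLE models for the fixture cell
fx_models <- function() {
  fixture("models", function() {
    gen <- fx_stimulus()
    cell <- fx_cell()
    wh <- fx_whitening()
    list(sta = lnp(gen$stimulus, cell$trains, method = "sta", whitening = wh$W),
         mle = lnp(gen$stimulus, cell$trains, method = "mle"))
  })
}

# homogeneous Poisson spike train over [0, duration)
poisson_train <- function(rate, duration, repetition_id = 1L) {
  n <- stats::rpois(1, rate * duration)
  spike_train(sort(stats::runif(n, 0, duration)), repetition_id = repetition_id,
              duration = duration)
}

# spike trains realizing exact per-bin counts of a 50 ms-binned histogram
trains_from_histogram <- function(counts, bin_s = 0.05, n_trials = 1) {
  times <- unlist(lapply(seq_along(counts), function(j) {
    k <- counts[j]
    if (k == 0) return(numeric(0))
    (j - 1) * bin_s + bin_s * (seq_len(k) - 0.5) / k
  }))
  lapply(seq_len(n_trials), function(r)
    spike_train(sort(times), repetition_id = r, duration = length(counts) * bin_s))
}

match_spike_times <- function(detected, truth, tol = 5e-4) {
  sens <- if (length(truth)) {
    mean(vapply(truth, function(t) any(abs(detected - t) <= tol + 1e-9), TRUE))
  } else NA_real_
  prec <- if (length(detected)) {
    mean(vapply(detected, function(t) any(abs(truth - t) <= tol + 1e-9), TRUE))
  } else NA_real_
  c(sensitivity = sens, precision = prec)
}
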