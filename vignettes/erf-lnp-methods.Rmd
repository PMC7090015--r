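---
title: "Estimating electrical receptive fields with linear-nonlinear-Poisson models"
author: "erflnp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating electrical receptive fields with linear-nonlinear-Poisson models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erflnp)
```

## The scientific problem

Retinal prostheses restore rudimentary vision by electrically stimulating
surviving retinal neurons, but pulsatile stimulation activates retinal
pathways indiscriminately. A promising alternative is to characterize each
retinal ganglion cell's (RGC) *electrical receptive field* — the temporal
current waveform it prefers — by stimulating with smooth Gaussian white-noise
currents and fitting an encoding model. `erflnp` implements that entire
computational chain for temporally smooth, 100 Hz band-limited noise delivered
through capacitive electrodes: stimulus synthesis, stimulation-artefact
removal, response metrics, two estimators of the linear-nonlinear-Poisson
(LNP) model, cross-validated firing-rate prediction, and population-level
clustering of the estimated filters. Because raw CMOS-MEA recordings are not
publicly deposited, the package ships a first-class synthetic-data generator
with known ground truth, so every stage admits recovery tests.

## The encoding model

The LNP model assumes the instantaneous firing rate is

$$\mu_t = \mathcal{N}(k^\top s_t),$$

where $s_t$ is the stimulus window spanning $-20\ldots+10$ ms around time bin
$t$ (300 samples at 10 kHz), $k$ is a 300-tap linear temporal filter, and
$\mathcal{N}$ is a static nonlinearity. Spikes are generated per 1 ms bin as
independent Bernoulli trials with probability $\mu_t$. The +10 ms "future"
taps are retained deliberately: residual stimulus correlations can push
apparent filter mass past the spike, and truncating the window would bias the
estimates.

Two estimators are provided:

* **Whitened STA** (`lnp(..., method = "sta")`). The stimulus is sliced into
  300-sample snippets 10 samples apart; the snippet covariance is
  eigendecomposed and the square root of its pseudo-inverse applied to every
  snippet; the whitened trace is reconstructed by tapered overlap-add; the
  filter is the average whitened window around each spike. The static
  nonlinearity is estimated as the binwise ratio of spike-triggered to full
  ensemble projection histograms and fitted by a sigmoid
  $y_{max}/(1+e^{-g(x-x_0)})+y_{min}$ or exponential $a\,e^{gx}+y_{min}$, the
  lower-residual form winning when unspecified.
* **Penalized maximum likelihood** (`lnp(..., method = "mle")`). Binary 1 ms
  spike labels are regressed on raw (unwhitened) snippets with a logit link
  and elastic-net penalty
  $\lambda[(1-\alpha)\tfrac12\lVert\beta\rVert_2^2+\alpha\lVert\beta\rVert_1]$;
  maximum-likelihood estimation performs the correlation correction
  implicitly. The negative log-likelihood is averaged over time-bin ×
  repetition rows; the intercept is never penalized and features are
  standardized internally.

Both return the same kind of S3 object with `print`, `summary`, `coef`,
`predict`, `plot`, `simulate`, `fitted` and `residuals` methods.

## Stimulus synthesis and its parameters

The voltage command is built from `stimulus_config()` parameters: a
cumulative sum of standard-normal steps with reflection limit
`reflect_limit = 10` AU (a step that would push the walk beyond the limit has
its sign inverted; reflection precedes filtering), low-passed by a causal
5th-order Butterworth filter at 100 Hz — a single forward pass, because the
physical stimulus was delivered causally — and affinely rescaled into the
safe command range $[0, 2.5]$ V. Because the electrode current is capacitive
($i = c\,dV/dt$), the current-proportional stimulus trace is the first
difference of the command. The trace is standardized to zero mean and unit
variance with the affine constants stored in metadata: the raw scale is a
hardware property, and standardization makes filter amplitudes comparable
across seeds. Defaults are 10 kHz and 5 s (50 000 samples, hence 4971
snippets). The spectral signature is a flat band to 100 Hz followed by a
steep roll-off; `band_power_ratio()` quantifies it as the median periodogram
ratio between the 110–500 Hz and 10–90 Hz bands.

## Numerical choices

* **Indexing and binning.** 0-based sample arithmetic internally; 1 ms bins
  are half-open $[t, t+1)$, a spike exactly on an edge belongs to the later
  bin; spike times are mapped to bins on the microsecond grid so
  floating-point representation cannot move an edge spike. Bins whose window
  exits the trace produce no sample anywhere (simulation, STA, GLM,
  prediction).
* **Whitening retention.** The pseudo-inverse keeps eigenvalues
  $\ge 10^{-7}\lambda_{max}$ (configurable; the rule is recorded in the
  operator). This retains roughly 32 of 300 modes, i.e. stimulus structure to
  ~500 Hz. A much stricter cut (e.g. $10^{-4}$) protects against amplifying
  suppressed modes but leaves the whitened trace correlated at millisecond
  lags (lag-1 ms autocorrelation ≈ 0.64, the sinc kernel of a ~280 Hz
  projector), defeating the purpose of whitening; at $10^{-7}$ the whitened
  trace decorrelates (max |acf| ≈ 0.05 over 1–20 ms) and its spectrum
  flattens, while STA recovery is unchanged. Much deeper cuts start
  amplifying estimation noise in the covariance tail.
* **Overlap-add reconstruction.** Whitened snippets are blended with a
  strictly positive "periodic" Hann taper normalized to unity at every
  covered sample, so the identity operator reproduces the input exactly and
  no sample is left without weight.
* **Elastic-net normalization and defaults.** The loss averages the Bernoulli
  negative log-likelihood over rows (the glmnet / scikit-learn convention);
  under this normalization the λ grid $[10^{-4}, 10^{-2}]$ spans from
  essentially unpenalized to visibly smoothing. The cross-validated 5 × 5
  grid search (`elasticnet_config()`) uses five *contiguous* folds — blocks
  respect the temporal correlation of the recording — and applies a
  one-standard-error rule toward the stronger penalty, because the
  validation-likelihood surface is nearly flat at desk scale and the argmin
  is noise. For repeated simulation studies the package defaults to the
  fixed ridge corner of the grid, $\lambda = 10^{-2}, \alpha = 0$: a smooth
  temporal filter is better matched by an L2 prior than by sparsity, and a
  fixed choice keeps large seed sweeps affordable. Repetitions are collapsed
  to binomial counts before optimization, which is mathematically identical
  to stacking rows and several times faster.
* **Nonlinearity histograms.** 25 equal-width bins spanning the central 99%
  of full-ensemble projections; bins with fewer than 5 ensemble counts are
  masked. Parametric fits start from 5 deterministic data-driven initial
  values; an exactly flat ratio short-circuits to the degenerate constant
  fit.
* **Cross-validation.** Five blocks of 1 s; models are fit on the other four
  seconds with a 30 ms guard so no training window crosses a block seam, and
  scored on the held-out second by Pearson correlation at 1 kHz against
  spike counts summed across repetitions. Zero-variance predictions score
  NaN with a flag and are excluded from means.
* **Clustering.** Mean-centered PCA with components sign-oriented so the
  largest-magnitude loading is positive; retained dimensionality is the
  smallest k reaching the variance target (default 90%). Average-linkage
  clustering runs on euclidean distances in PC space; the automatic cut
  takes the largest relative gap among the last 10 merge heights and is
  always overridable, mirroring a by-eye dendrogram cut. `select_pcs` exists
  because a component can be dominated by nuisance (e.g. between-recording)
  variance — or, in synthetic data with isotropic tap noise, because the
  trailing near-equal eigenvalues carry no class structure; clustering is
  then run on the leading components only. Filters enter PCA unnormalized
  (an L2 option exists but is off by default).

## What the synthetic data emulates — and what it does not

`simulate_lnp_spikes()` draws Bernoulli spikes from template filters
(`make_template_filter()`) of the three archetypes observed in wild-type
retina — monophasic negative (default peak −3.7 ms), monophasic positive
(−5.5 ms) and biphasic (+0.2 / −5.2 ms lobes) — built from Gaussian lobes of
2 ms width, with a sigmoid nonlinearity calibrated by root finding so the
mean rate hits a target (default 40 spikes/s). `synthesize_raw_recording()`
reproduces the raw-recording regime in which the stimulation artefact
(default gain 100 × a unit-variance stimulus) exceeds the 1 ms biphasic
spike template (peak 1) by ≥ 40 dB RMS. `generate_light_responses()` builds
inhomogeneous Poisson responses to a 1 Hz flicker whose decay constant is
solved so the expected transiency index matches a requested value.

The generator deliberately omits several features of real recordings:
spike-sorting errors and bursting/refractory structure (spikes are
conditionally independent given the stimulus), electrode-geometry and
current-spread effects, nonstationary excitability, and any network
nonlinearity beyond a single static function. Passing recovery tests
therefore demonstrates correctness of the estimators under the model's own
assumptions, not robustness to every violation found in tissue.

The published 1000–9500 Hz artefact band-pass presumes hardware-rate
recordings; synthetic traces share the 10 kHz stimulus grid, so the
preprocessing chain caps the upper edge at 0.95 × Nyquist (4750 Hz). The
2nd-order Bessel design is built from the analog prototype (poles of
$s^2+3s+3$) and digitized by band transform plus bilinear mapping, applied as
a single causal pass like the online hardware filter.

## Design choices on genuinely open points

* The artefact factor $f = r^\top S / S^\top S$ is estimated after band-pass
  filtering *both* signals, then subtracted: the projection is only
  meaningful when both live in the same passband. The unfiltered order is
  available via `filter_first = FALSE`.
* The leave-one-out reliability index generalizes the 4-vs-1 histogram
  correlation to n repetitions; summed versus averaged pooled histograms are
  equivalent under Pearson correlation.
* The transiency histogram is normalized by its maximum bin — the only
  reading under which the printed extremes 0 (uniform) and $1-1/10$ (first
  bin only) both hold. The preferred phase follows the bias-index class,
  averaging both phases for ON-OFF cells.
* Sigmoid-versus-exponential selection for the STA nonlinearity uses the
  lower least-squares residual.
* The STA uses the reconstructed whitened trace (not per-spike whitened
  snippets); predictions from STA models project the whitened stimulus,
  predictions from MLE models the raw stimulus, each matching the space its
  filter was estimated in.
* Prediction pools spike counts across repetitions at 1 kHz; single
  repetitions can be scored through `prediction_performance()` directly.
* One master seed expands into per-stage child seeds through a deterministic
  counter scheme (`derive_seed()`), recorded in pipeline outputs.

## Problem sizes in the test suite

The packaged studies run at the study's native scale: 5 s × 10 kHz stimulus,
5 repetitions, ~40 Hz cells; parameter-recovery sweeps use 20 seeds per
archetype at 5 s and at 25 s; the clustering study uses 60 filters (20 per
archetype, 20% tap noise); the prediction–reliability study uses 50 cells on
a gain gradient with a single 4 s/1 s split per cell; the demo pipeline runs
three cells through every stage with both estimators. These sizes were chosen
so the complete suite documents the method's behaviour while remaining
comfortably runnable on a laptop.

## Known limitations

* Temporal-only filters: no spatial or spatiotemporal receptive-field
  estimation, electrode geometry is out of scope.
* The Bernoulli likelihood clips multiple spikes per 1 ms bin to one; at
  40 Hz this is rare, but very high rates would need finer bins.
* The threshold spike detector is a stand-in for proper spike sorting and is
  only meant to close the loop on synthetic raw traces.
* The histogram-ratio nonlinearity is only constrained inside the range of
  observed projections; predictions extrapolate through the fitted
  parametric form.

## A worked example

```{r example, eval = FALSE}
gen <- generate_stimulus(stimulus_config(seed = 3))
neuron <- lnp_neuron(make_template_filter("biphasic"))
trains <- simulate_lnp_spikes(neuron, gen$stimulus, n_repetitions = 5, seed = 11)

model <- lnp(gen$stimulus, trains, method = "sta")
summary(model)
plot(model)

cv <- run_blockwise_cv(gen$stimulus, trains, method = "sta", linear_only = TRUE)
cv
```
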