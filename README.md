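# subunitscope

Simulation and system-identification toolkit for studying how direction
selectivity (DS) is constructed in primary visual cortex. It is aimed at
computational neuroscientists who want to test spike-triggered and
cascade-model analyses against model neurons with known ground truth:
V1 complex cells respond to motion direction while being invariant to
spatial phase, and the question is whether that computation looks like a
single *quadrature pair* of space-time filters (the motion-energy
description) or like many small, spatially *localized* subunit filters
pooled across the receptive field.

## What it computes

Given a spatiotemporal stimulus movie `s` and a spike train binned at the
frame rate, the package implements the full identification chain:

* **STA / STC.** The spike-triggered average, and the eigendecomposition
  of `ΔC = C_spike − C_all` (spike-conditioned minus ensemble stimulus
  covariance). Eigenvectors with significantly increased variance are
  excitatory, with decreased variance suppressive; significance comes
  from a circular spike-shift null. For correlated stimuli the analysis
  runs in a PCA-whitened space `Z = S V D^{-1/2}` with smoothed
  back-mapping `b = V D^{1/2} b_w`.
* **Localization.** Within the significant STC subspace, filters
  `k_β = Σ_i β_i b_i` are found that minimize the power-weighted spatial
  spread `L(c, β) = Σ_x R_β(x) (c − x)²` subject to `Σ β_i² = 1`, where
  `R_β(x)` is the temporal power (variance across lags) at position `x`
  — yielding compact, simple-cell-like subunits at each target location
  `c`, summarized by aligned PCA.
* **Cascade model (GNM).** A generalized nonlinear model
  `r(t) = F[Σ_i Σ_τ h_iτ f_i(k_i·s_{t−τ}) − θ]` with softplus spiking
  `F(u) = log(1+e^u)`, per-filter tent-basis nonlinearities `f_i` and
  short temporal kernels `h_i`, fit by penalized Poisson maximum
  likelihood; relevant localized filters are selected by L1-logistic
  regression on their rectified outputs.
* **Tuning metrics.** DSI `= (R_p − R_np)/(R_p + R_np)` and modulation
  index `MI = F1/DC` from simulated grating responses, the spectral
  `DSI_RF = (Q1 − Q2)/(Q1 + Q2)` from a filter's Fourier quadrants, SVD
  decomposition of DS filters into separable non-DS parts, and
  preferred-axis projection of 3-D (pixel-movie) filters.

Model neurons for validation span LN simple cells, separable-input
simple cells, energy-model complex cells and pooled-subunit complex
cells, all with Poisson spiking; stimulus generators cover binary
m-sequence bar movies, drifting gratings, and Gaussian/1-over-f noise
movies.

## Worked example

Simulate an energy-model complex cell driven by a binary m-sequence bar
movie, recover its subspace, fit the cascade, and predict its grating
tuning:

```r
library(subunitscope)

movie  <- generate_bar_stimulus(n_bars = 16, n_frames = 50000, mseq_order = 15)
design <- embed_stimulus(movie, n_lags = 12)
pair   <- list(make_gabor_strf(16, 12, spatial_freq = 3,
                               tilt_phase_per_lag = 0.5, phase = 0),
               make_gabor_strf(16, 12, spatial_freq = 3,
                               tilt_phase_per_lag = 0.5, phase = pi/2))
cell   <- neuron_spec("energy_complex", pair, gain = 1, offset = -3)
spikes <- poisson_spikes(neuron_rate(cell, design), seed = 1)
spikes
#> <spike_counts> 50000 frames, 31936 spikes (mean 0.639/frame)

stc <- compute_stc(design, spikes)
stc <- select_significant(stc, "shuffle", design = design, spikes = spikes,
                          n_shuffles = 60, alpha = 0.01, seed = 2)
stc
#> <stc_result> 192 dims, 31936 spikes; top eigenvalues: 1.72, 1.71, 0.949
#>   significant: 6 excitatory, 9 suppressive

fit <- fit_nonlinearities(stc_subspace(stc, "excitatory"), design, spikes,
                          knots = 15, folds = 5)
fit$report
#> <gnm_fit_report> train LL +0.8111 nats/spike; xval +0.8066 nats/spike (5 folds)

grating_tuning(fit$model, sf_grid = c(2, 3, 4), tf_grid = c(2, 4, 6))
#> <tuning_metrics> DSI=0.983 (signed 0.983), MI=0.019 @ sf=3, tf=6 Hz, dir=+1
```

The two leading eigenvalues (1.72, 1.71) are the quadrature pair; the
fitted cascade predicts the cell's grating behavior — strongly direction
selective (DSI 0.98), phase invariant (MI 0.02, far below the simple-cell
boundary of 1) — matching the generator's own tuning (DSI 0.998,
MI 0.005). The extra "significant" eigenvalues beyond the true pair
illustrate two things the vignette discusses: with this much data the
shuffle null is sensitive to weak but real structure, and binary ±1
stimuli induce genuine negative eigenvalues for squaring nonlinearities
(a fourth-moment property of the stimulus, absent under Gaussian noise).

A one-command version of the whole chain, with per-stage outputs and a
reproducibility manifest, is `run_pipeline()`; a shell front end with
subcommands (`simulate-stimulus`, `stc`, `localize`, `fit-gnm`,
`tuning`, `run`) is installed at `inst/cli/subunitscope.R`.

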