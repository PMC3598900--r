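---
title: "Inferring localized subunit filters in V1 model neurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring localized subunit filters in V1 model neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subunitscope)
```

## The problem

Direction-selective (DS) complex cells in primary visual cortex respond to
the direction of visual motion while being invariant to spatial phase. The
classical motion-energy account builds this from a *quadrature pair*: two
space-time-tilted filters, 90 degrees apart in phase, whose squared outputs
are summed. But a quadrature pair is a mathematically compact description,
not necessarily a circuit diagram: the same subspace of stimulus
selectivity is equally well described by many *localized* filters --
small, simple-cell-like subunits tiling the receptive field, each feeding
a rectifying or squaring nonlinearity whose outputs are pooled.

`subunitscope` implements the full identification chain needed to ask
which description the data supports, for simulated neurons with known
ground truth:

1. **Stimulus generation** -- binary m-sequence bar movies, drifting
   gratings, Gaussian and 1/f "pink" noise movies, and their temporal
   embedding into a design matrix.
2. **Model neurons** -- LN simple cells, separable-input simple cells,
   energy-model complex cells, and pooled-subunit complex cells, all with
   softplus spiking nonlinearities and Poisson spike generation.
3. **Spike-triggered estimation** -- STA, STC eigenanalysis with
   shuffle-based significance, and PCA whitening for correlated stimuli.
4. **Localization** -- rotating the significant STC subspace into
   spatially compact filters.
5. **Cascade modeling** -- a generalized nonlinear model (GNM) with
   fitted per-filter nonlinearities, estimated by penalized Poisson
   maximum likelihood, plus L1-logistic selection of relevant filters.
6. **Tuning prediction** -- direction-selectivity (DSI) and modulation
   (MI) indices from simulated grating responses, and the spectral
   DSI of a filter from its Fourier quadrants.

## Spike-triggered estimation

With the stimulus embedded so that row $t$ of the design matrix $S$
holds the frames at lags $0 \dots L-1$ before bin $t$, the STA is the
spike-count-weighted mean of $S$ minus the ensemble mean, and STC
analysis eigendecomposes

$$\Delta C = C_\text{spike} - C_\text{all},$$

the difference between the spike-conditioned and ensemble stimulus
covariance (both mean-subtracted; bins with $k$ spikes enter with weight
$k$, consistent with the Poisson likelihood used later). Eigenvectors
with significantly increased variance are *excitatory*, with decreased
variance *suppressive*. Significance uses a conservative,
stimulus-preserving null: the spike train is circularly shifted by at
least $L$ bins, $\Delta C$ is recomputed, and the extreme eigenvalues of
many such shifts form a two-sided envelope (default $\alpha = 0.01$,
100 shifts). The STA is deliberately not projected out of the STC.

Two conventions make results deterministic: eigenvalues are sorted in
descending order, and each eigenvector's largest-magnitude entry is made
positive.

**A property worth knowing about binary stimuli.** STC's clean separation
of excitatory and suppressive subspaces assumes a spherically symmetric
(Gaussian) stimulus ensemble. Binary $\pm 1$ bar stimuli have fourth
moments below Gaussian ($E[s^4] = 1$ vs. 3), and for squaring
(energy-model) neurons this deficit produces genuine *negative* STC
eigenvalues in directions that spatially overlap the true filters --
spurious "suppression" that is a property of the stimulus, not the
neuron. The package's recovery tests therefore probe STC-based pipelines
with Gaussian white noise (`generate_pink_noise_movie(exponent = 0)`)
and reserve the m-sequence for STA recovery, where the effect is absent.
Users applying the shuffle test to binary-stimulus recordings of
strongly nonlinear cells should expect, and discount, this class of
suppressive eigenvalue.

### Whitening for correlated stimuli

For pink-noise or naturalistic movies the raw STC is biased by stimulus
correlations. `whiten_design()` projects the design matrix onto its
first $M$ principal components and rescales to unit variance,
$Z = S V D^{-1/2}$; spike-triggered analyses then run in $Z$.
`dewhiten_filter()` maps estimates back with $b = V D^{1/2} b_w$, which
re-weights stimulus dimensions by their standard deviation. This is a
deliberate bias-variance choice: it smooths estimates toward the
stimulus covariance (the recovered filter is effectively $C k$ rather
than $k$), which suppresses noise in poorly sampled dimensions at the
cost of low-pass distortion. On an exactly white stimulus the
whitened and direct routes agree; on 1/f noise the recovered filter is a
covariance-smoothed version of the truth, and the package's tests
bound how much of the planted filter survives (correlation about 0.8 for
a mid-frequency Gabor under exponent-1 pink noise). The default
$M = 600$ suits large pixel-movie embeddings; for the 256-dimensional
bar examples here we retain 120--256 dimensions.

## The localization cost

Any unit-norm coefficient vector $\beta$ on the significant STC filters
$\{b_i\}$ gives a filter $k_\beta = \sum_i \beta_i b_i$ in the same
subspace. Its *temporal power* at position $x$ is the variance of its
weights across lags,

$$R_\beta(x) = \frac{1}{T}\sum_t \left[\langle k_\beta(x,\cdot)\rangle
- k_\beta(x,t)\right]^2,$$

and the localization cost centered at $c$ is

$$L(c, \beta) = \sum_x R_\beta(x)\,(c - x)^2, \qquad
\sum_i \beta_i^2 = 1.$$

Distances are in bar-index units (squared Euclidean pixel distance for
2-D stimuli). Because $R_\beta$ is quadratic in the filter and the
filter is linear in $\beta$, $L$ is a quadratic form
$\beta^\top Q(c)\,\beta$; the constrained minimum is therefore a global
one, and the package verifies its optimizer against the closed-form
smallest-eigenvector solution of $Q(c)$ in its test suite. The
production path optimizes the normalized Rayleigh quotient by BFGS from
20 random unit starts (seeded; ties below $10^{-10}$ broken by restart
order), which generalizes unchanged if a future cost is not quadratic.
Additional filters at the same center come from re-optimizing in the
orthogonal complement of the ones already found; excitatory and
suppressive subspaces are localized separately by default.

A useful invariance follows from the subspace view: the achieved cost
depends only on the span of the basis, not its coordinates, so any
orthonormal rotation of the STC filters leaves it unchanged (tested to
$10^{-6}$), and enlarging the basis can only lower it.

The localized family is summarized by aligning each filter so its
temporal-power centroid sits at the grid center (nearest-integer shift,
zero filling -- no interpolation, avoiding resampling artifacts) and
running an uncentered PCA on the stack. For a pooled-energy neuron two
components -- a quadrature pair -- carry nearly all variance.

## The cascade model (GNM)

Given fixed filters $k_i$, the firing rate is

$$r(t) = F\!\left[\sum_i \sum_\tau h_{i\tau}\,
f_i(k_i \cdot s_{t-\tau}) - \theta\right],
\qquad F(u) = \log(1 + e^u),$$

with bin width one frame. Each $f_i$ is piecewise linear on a tent basis
(default 20 knots at empirical quantiles of $k_i \cdot s$, spanning the
0.5--99.5 percentile range with flat extrapolation beyond), each $h_i$ a
short nonnegative-lag kernel (default length 1, i.e. instantaneous,
configurable). Fitting maximizes the Poisson log-likelihood
$\sum_t [n_t \log r_t - r_t]$ minus squared second-difference penalties
$\lambda_f \|D_2 f_i\|^2$ and $\lambda_h \|D_2 h_i\|^2$, by BFGS on the
$(f, \theta)$ block, alternating with an $h$ block when $h$ is longer
than one bin, until the relative objective change falls below $10^{-6}$.
Identifiability is fixed by $f_i(\text{median}) = 0$ (absorbed into
$\theta$) and $\|h_i\| = 1$ (scale absorbed into $f_i$). Degenerate
filters (constant output) and fits with fewer than 100 spikes are
rejected with errors.

Model comparison uses cross-validated log-likelihood improvement over a
constant-rate model, in nats per spike, on contiguous time blocks
(never random frames -- the data are autocorrelated). Note that a paired
comparison across folds is extremely sensitive: the two models see
nearly identical data, so fold-to-fold noise in the *difference* is of
order $10^{-3}$ nats/spike, and even scientifically negligible
systematic differences (e.g. the overfitting cost of a few extra knots)
can exclude zero. The package's equivalence check for the
separable-input description of a DS simple cell therefore gives both
models their exact filter sets -- the true DS filter for the LN model,
its two SVD components for the separable model -- so that both can
represent the generator exactly and the paired interval isolates pure
parameterization cost. With estimated filters instead, the two-filter
model systematically (if slightly) wins, because it can refit the filter
within the plane its components span while the LN model is stuck with
the noisy STA direction.

Sparse selection of relevant localized filters follows the standard
route: features are the half-wave-rectified outputs of each candidate
and its negative, the target is the binarized spike train, and
`glmnet`'s L1-penalized logistic regression with contiguous
cross-validation folds picks the penalty; filters with any nonzero
coefficient survive.

## Tuning indices

`grating_tuning()` probes a generator or fitted model with drifting
gratings over a frequency grid in both directions, discards one
transient cycle, and uses an integer number of steady-state cycles
(default 8). DSI is $(R_p - R_{np})/(R_p + R_{np})$ at the preferred
grating; the signed variant is positive when drift toward increasing $x$
dominates. MI is $F_1/\mathrm{DC}$, with $F_1$ the discrete Fourier
amplitude at the grating's temporal frequency. Classical benchmarks
hold by construction: an energy-model cell is phase invariant
(MI $\approx 0$) and strongly DS; a half-wave-rectified LN cell at
threshold has MI $= \pi/2$; a space-time-separable cell has DSI
$\approx 0$.

`dsi_from_rf()` computes the same directional contrast from a filter
alone as $(Q_1 - Q_2)/(Q_1 + Q_2)$, where $Q_1, Q_2$ sum the Fourier
*power* (squared magnitude; amplitude would also work, power is the
motion-energy convention) over the two spectral quadrants. The
zero-frequency row and column are excluded -- the formula is ill-defined
on the axes, and exclusion keeps the quadrants disjoint -- as is the
unpaired Nyquist row/column of even-sized grids, which makes two exact
symmetries hold to machine precision: separable filters give exactly 0,
and mirroring a filter in space exactly negates the index.

For 2-D pixel stimuli, `project_preferred_axis()` rotates each spatial
slice so the preferred-motion axis (estimated from the dominant spatial
frequency at the peak-power lag, reported as an axial angle) is
horizontal, sums over the orthogonal coordinate, and yields an x-t
filter comparable to the bar-stimulus case.

## What the synthetic generators emulate -- and what they do not

The generators reproduce the stimulus classes and neuron archetypes of
classical V1 experiments: 100 Hz binary bar movies driven by a built-in
table of maximal-length shift registers (orders 2--16; successive
non-overlapping windows of the periodic sequence fill each frame, so the
bar covariance over a period is identity minus an order-$1/P$ term),
50 Hz pink-noise movies shaped in the 3-D Fourier domain with the DC
term zeroed, and drifting gratings. Simulated recordings at the default
operating points produce roughly 0.3--1.7 spikes per frame and $10^4$ to
$10^5$ total spikes, inside the range of the electrophysiological
recordings this methodology was built for.

Passing tests on these simulations show that the estimation chain
recovers the structure it was designed to recover under its own
generative assumptions: Poisson spiking from a static cascade, stationary
stimuli, no adaptation, no spike-history dependence, no correlated noise
across time, and subunits that are exact spatial translates of one
prototype. Real recordings violate all of these to some degree; in
particular the tests say nothing about robustness to non-Poisson firing,
eye movements, or slow nonstationarities. Problem sizes in the tests
(16 bars, 12--16 lags, $2\times10^4$ to $2\times10^5$ frames, 40--100
shuffle recomputations) were chosen as the smallest at which the
recovery properties are stable and well separated from their failure
thresholds.

## Known limitations

* Only the quadratic-spread localization cost is implemented; other
  localization measures are reported to behave similarly but are not
  provided.
* Filters are never refit inside the GNM; the cascade inherits whatever
  bias the STC/localization stage leaves.
* The shuffle null is the only data-driven significance method
  implemented (plus fixed counts); eigenvalue-distribution heuristics
  and nested cross-validation are not.
* 2-D (pixel-movie) support covers generation, embedding, whitening,
  localization cost and projection, but the aligned-PCA summary is 1-D
  only.
* `dsi_from_rf()` assumes the filter is sampled finely enough that its
  spectral mass is away from the Nyquist boundary.

## A minimal end-to-end run

```{r pipeline, eval = FALSE}
manifest <- run_pipeline(list(
  stimulus = list(n_frames = 20000),
  estimation = list(selection = "fixed", n_pos = 4),
  localization = list(n_centers = 5),
  gnm = list(knots = 10, folds = 3)
))
manifest$report
```

The manifest records the config hash, per-stage output paths and the
tuning report (DSI, MI, cross-validated log-likelihood improvement,
filter counts); re-running the same configuration reproduces every
number bit-identically.
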