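---
title: "Pooled scale invariance: model, estimators, and the synthetic testbed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled scale invariance: model, estimators, and the synthetic testbed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolsi)
```

## The scientific problem

Receptive fields (RFs) in primary visual cortex are classically modelled
as scale invariant: a Gabor whose shape is independent of its scale, so
that RF width is inversely proportional to the preferred spatial
frequency $f_o$, linear SF bandwidth is proportional to $f_o$, and
orientation bandwidth and phase selectivity do not depend on $f_o$ at
all. Dense two-photon measurements within a hypercolumn contradict every
one of these predictions: most cells are wider than one carrier period,
the spread of RF widths is far narrower than scale invariance allows,
and orientation bandwidth and F1/F0 both co-vary with $f_o$.

`poolsi` implements the model that reconciles these observations —
*pooled scale invariance* — together with everything needed to exercise
it end to end on synthetic data: generators for cortical functional maps
and neuron populations, simulated two-photon movies and response
kernels, the imaging pipeline, the tuning-curve fits, the pooling
parameter estimators, cross-validated model comparison, and
functional-clustering statistics.

## The model

A scale-invariant input at preferred SF $f_o$ has

$$\sigma_{x,\mathrm{si}} = \frac{1}{\alpha f_o}, \qquad
  \sigma_{f,\mathrm{si}} = \frac{\alpha f_o}{2\pi}, \qquad
  \sigma_{\log f,\mathrm{si}} = \log_2\!\left(1 + \frac{\alpha}{2\pi}\right), \qquad
  \sigma_{\theta,\mathrm{si}} = \arctan\frac{\alpha}{2\pi A},$$

with scaling coefficient $\alpha$ (default $\pi$, consistent with 2–3
ON/OFF subfields) and envelope aspect ratio $A$ (default 2). At the
defaults, $\sigma_{\theta,\mathrm{si}} \approx 14^\circ$ and the log
bandwidth is $\log_2 1.5 \approx 0.585$ octaves. (Some treatments quote
$\approx 0.7$ octaves for this constant; the expression itself evaluates
to 0.585 at $\alpha=\pi$, and the package returns the expression's
value.)

A measured neuron is modelled as a Gaussian-weighted superposition of
such inputs — pooling over retinotopy with window $\sigma_{h(x)}$
(degrees) in the spatial domain, and over the 2D Fourier plane with an
isotropic window $\sigma_{h(f)}$ (cyc/deg) in the spectral domain.
Because the superposition acts as a convolution of the envelope with the
pooling window, variances add:

$$\sigma_{x,p}^2 = \sigma_{x,\mathrm{si}}^2(f_o) + \sigma_{h(x)}^2,
\qquad
\sigma_{f,p}^2 = \sigma_{f,\mathrm{si}}^2(f_o) + \sigma_{h(f)}^2.$$

Orientation bandwidth follows from the same spectral window with **no
extra parameter**: the tangential width of the pooled spectral energy at
radius $f_o$ is $\sqrt{\sigma_{f,\mathrm{si}}^2/A^2 + \sigma_{h(f)}^2}$,
so $\sigma_{\theta,p} = \arctan\!\big[\sqrt{\sigma_{f,\mathrm{si}}^2/A^2
+ \sigma_{h(f)}^2}\,/ f_o\big]$.

Phase selectivity follows from pooling half-wave-rectified inputs whose
absolute spatial phase advances at a rate $D \in [0,1]$ times the
retinotopic rate ($D=1$: constant relative phase; $D=0$: constant
absolute phase):

$$F1/F0 = \pi \exp\!\big[-(\sigma_{h(x)}\, 2\pi f_o D)^2 / 2\big],$$

a Gaussian in $f_o$ with SD $(\sigma_{h(x)} 2\pi D)^{-1}$ — 0.66 cyc/deg
at $\sigma_{h(x)}=0.24^\circ$, $D=1$. The ceiling $\pi$ is the F1/F0 of
a single half-wave-rectified sinusoid.

The three pooling parameters are estimated sequentially, exactly
mirroring the model structure: $\sigma_{h(x)}$ from RF widths (root of
the median of $\sigma_{x}^2 - \sigma_{x,\mathrm{si}}^2$), then $D$ by 1D
least squares on the $(f_o, F1/F0)$ cloud with $\sigma_{h(x)}$ held
fixed, and $\sigma_{h(f)}$ by the same root-median estimator on SF
bandwidths. The median (rather than the mean) makes the estimator
robust to the long upper tail of measured widths; a non-positive median
— a population at or below scale invariance — raises an explicit
estimation-failure condition rather than returning 0.

```{r}
si <- si_params()
pool <- pooling_params(sigma_hx = 0.24, sigma_hf = 0.85, D = 0.54)
fo <- c(0.5, 1, 2, 4, 8)
data.frame(fo = fo,
           rf_width = round(pooled_rf_width(fo, si, pool), 3),
           sf_bw = round(pooled_sf_bandwidth(fo, si, pool), 3),
           ori_bw = round(pooled_ori_bandwidth(fo, si, pool), 1),
           f1f0 = round(pooled_f1f0(fo, pool), 3))
```

## Numerical simulations as oracles

The closed forms above are checked against direct numerical
superpositions (`simulate_spatial_pooling()`, `simulate_phase_pooling()`,
`simulate_spectral_pooling()`): shifted copies of the scale-invariant
input, Gaussian-weighted on a grid of offsets spanning $\pm 4$ pooling
SDs, summed and re-measured. The spatial and spectral simulations shift
*fixed-shape* copies of the input at $f_o$ (the convolution picture), so
variance addition is exact in the refined-grid limit; pooling across
inputs whose own widths vary with their location is not simulated, and
the closed forms are first-order in that respect. The phase simulation
sums rectified cosines and recovers F1/F0 from the fundamental of the
summed curve. Grid-convergence tests put the simulations within 2%
(widths) and 5% (F1/F0) of the closed forms; those tolerances come from
the convergence tests themselves, not from any empirical target.

## The synthetic testbed

No raw in vivo imaging data ship with the package; every stage is
instead validated against a generator whose ground truth is known
exactly.

**Cortical sheets** (`make_cortical_sheet()`). The preferred-SF map is
band-pass-filtered Gaussian noise (annular Gaussian band centred on a
750 µm period, relative width 0.25), exponentiated so log2($f_o$) has
mean 0.95 and SD 0.64 — the marginal calibration used throughout, taken
from `v1_reference_marginals()`. Orientation maps are the half-angle of
band-pass-filtered complex noise, which yields pinwheels at the same
spatial scale. Retinotopy is a linear gradient at 2 mm/deg, and the
absolute-phase map advances at $D \times 2\pi f_o$ per degree of
retinotopy, the literal reading of the phase-progression coefficient.
Band-pass synthesis was chosen because the map period and the marginal
distribution can be controlled independently; real maps' cross-map
alignment (e.g. pinwheel centres sitting on low-$f_o$ domains) is *not*
emulated, so clustering tests validate the statistics, not the joint
geometry of real maps.

**Populations** (`sample_population()`). Each neuron's noiseless tuning
follows the pooled closed forms at its map-given $f_o$. Measured-
parameter targets add multiplicative log-normal scatter (SD 0.2 in
natural log units) on widths and truncated Gaussian noise (SD 0.15,
clipped to $[0,\pi]$) on F1/F0; the data give no noise model, so these
magnitudes were fixed once at values typical of two-photon tuning
measurements and are config-exposed.

**Response kernels and movies.** Grating kernels are separable
orientation × SF × phase amplitude profiles times a double-exponential
calcium impulse response (50 ms rise, 400 ms decay — plausible for a
fast genetically encoded indicator; the kinetics are config-exposed).
The phase profile is a rectified cosine plus a baseline chosen so that
the four-point sine-fit measurement recovers the neuron's target F1/F0
exactly wherever the required baseline is non-negative; near the
rectifier ceiling the baseline clips at zero and the measured ratio
saturates at the grid's rectifier value (4.0 on an aligned 4-phase grid,
vs $\pi$ in the dense-phase limit), a deliberate, documented consequence
of coarse phase sampling. Bar kernels project a 2D Gaussian envelope
(length $A\sigma_x$) onto the probe axis, modulate it by a phase-locked
carrier weighted by $F1/F0\,/\pi$ (so complex cells get overlapping
ON/OFF envelopes), scale by an orientation gain at the neuron's
bandwidth, and smear by the 0.2° bar (boxcar convolution; variance
$w^2/12$, removable with `correct_bar_width()`). Bar length is fixed at
3°. Movies place 3 µm Gaussian puncta on a static neuropil texture, add
shared breathing/heartbeat sinusoids, white noise, and optional integer
drift, and always emit ground-truth masks.

## Imaging pipeline choices

* **Alignment** uses cross-correlation between *successive* frames with
  cumulative shifts: consecutive frames share content, so the increment
  is unambiguous even while different cells blink on and off
  (reference-frame alignment fails exactly this way on sparse movies).
* **Cell detection**: the local cross-correlation image (per-pixel sum
  over time of fluorescence times its DoG-weighted neighborhood, center
  σ 3 µm, surround σ 20 µm, both integral-normalized) replaces manual
  point-and-click with a deterministic detector: local maxima above a
  robust global threshold seed region growing at half the seed value.
  A mask-import path (`extract_traces()` accepts any labeled mask)
  preserves the manual workflow.
* **Notch filter**: peaks are detected on a Welch-averaged power
  spectrum in a 0.2–3 Hz search band (config-exposed) and must stand
  3 robust SDs above the local floor *and* 4 dB above it; without the
  averaging and prominence gate, χ² fluctuations of a featureless
  spectrum trigger spurious notches on about a third of plain noise
  traces. Removal is zero-phase spectral magnitude interpolation, which
  cannot distort the timing of triggered averages and is idempotent.
* **Triggered averaging** spans 1 s (15 frames) after onset. With 133 ms
  updates, responses overlap heavily; the stimulus-independent pedestal
  this adds to every condition is removed by per-timepoint condition-
  mean subtraction when kernels are compared.

## Fitting rules

Tuning curves come from the temporally collapsed kernel (50 ms Gaussian
smoothing, slice at the global peak, earliest frame on ties).
Orientation: 4-parameter Gaussian after circular shift, bandwidth =
half-width at 61% of amplitude ($\approx 0.994\sigma$; for fits with
$\sigma > 90^\circ$ the half-width is measured on the curve and capped
at 90°). SF: 5-parameter difference-of-Gaussians on the linear axis,
$f_o$ = argmax of the fit, bandwidth = (f_hi − f_low)/2 at 61% of the
peak with f_low falling back to 0.25 cyc/deg when the fit never crosses
below the peak; a fitted peak at the minimum SF flags the cell low-pass.
Phase: fixed-period sine with free amplitude, phase and offset (the
minimal parameterization), F1 = fitted peak-to-peak, F0 = mean, cells with
F0 ≤ 0 flagged. Bar RFs: orientation and position axes binned 2× before
the 1D Gaussian fits; the RF centre comes from a rotated 2D Gaussian fit
to the filtered back-projection of the *unbinned* envelope sinogram
(9-angle reconstructions show severe limited-angle streaks, so binning
is applied only where the fitting rule states it). All nonlinear fits
use grid-seeded, bounded Levenberg–Marquardt (σ bounded in [half grid
step, full range]); inclusion requires 70% variance explained per the
relevant fit, low-pass cells are excluded from statistics but retained
for plotting, and every exclusion is counted in an audit log.

## Cross-validation and comparison models

`loocv_compare()` refits each candidate model with one cell held out and
scores $[\log_2(\text{data}) - \log_2(\text{prediction})]^2$; pooled
scale invariance is compared against fixed-α scale invariance and
against a *flexible* scale invariance whose single coefficient is refit
in log space (the conservative comparison). The paired test on per-cell
squared-error differences is a t-test as specified; a Wilcoxon
signed-rank p is reported alongside but is not the default decision
rule.

## Known limitations and degenerate inputs

* The magnification estimator (through-origin slope of pairwise mm vs
  deg) is attenuated by RF-centre measurement error in its x coordinate;
  with 0.05° jitter on a 0.5°×0.35° field the bias is about −10%, and
  jitter-free inputs recover the slope exactly. The estimator follows
  the stated measurement procedure; no errors-in-variables correction is
  applied.
* The four-point phase grid biases F1/F0 upward near the simple-cell
  ceiling (4.0 vs π); ratios below ~2.8 are measured essentially
  unbiased.
* Degenerate inputs are explicit errors, not silent defaults:
  zero-variance traces (`poolsi_zero_variance`), populations at or below
  scale invariance (`poolsi_estimation_failure`), all-zero kernels,
  movies shorter than 2 frames, search bands outside Nyquist, map
  periods inconsistent with the grid.

## Problem sizes

The shipped tests and the acceptance script use the sizes at which the
estimators were characterized: recovery runs use n = 200 cells (widths)
and n = 150 (phase) with 100 replicates, magnification runs n = 100
cells with 50 replicates, cross-validation n = 150, the end-to-end movie
check 8 cells × 40 presentations per condition in 10 blocks, and the
shuffle tests 99–1000 permutations. The full pipeline scales linearly
in cells, frames and permutations from these values.
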