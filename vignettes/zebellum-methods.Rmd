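---
title: "Sensorimotor encoding analysis of cerebellar recordings: models and methods"
author: "zebellum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sensorimotor encoding analysis of cerebellar recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zebellum)
```

# The scientific problem

In the larval zebrafish, essentially the whole cerebellum is optically and
electrophysiologically accessible, which makes it possible to ask — cell by
cell — what each Purkinje cell encodes while the animal sees moving visual
scenes and produces (fictive) swim bouts. Purkinje cells emit two spike
types: rare, large **complex spikes (CS)** driven by climbing fibers, and
fast **simple spikes (SS)** modulated by granule-cell parallel fibers.
zebellum implements the full analysis chain for this kind of experiment:

1. extract CS/SS trains from cell-attached voltage traces;
2. extract swim bouts, vigor, and the fictive swim frequency from
   ventral-root (VR) recordings, and eye kinematics from eye traces;
3. build stimulus and motor feature regressors, optionally convolved with a
   GCaMP response kernel for imaging data;
4. fit penalized linear encoding models to spiking and fluorescence
   signals, classify each cell's CS response phenotype, and quantify
   sensory-versus-motor contributions;
5. compute spike-interaction statistics (CS-triggered SS histograms by
   behavioral context, bout-triggered rates, autocorrelation tests,
   direction selectivity, response latencies);
6. cluster population responses and quantify their spatial organisation
   (anatomical clustering and stereotypy indices);
7. count nuclei in 3D image volumes and measure dendritic planarity.

Because the real recordings of any given study are not redistributable, the
package ships a first-class **synthetic-data module** whose generative
defaults are the population statistics such an experiment reports. Every
downstream stage is then testable by parameter recovery: the generator
plants a number, the pipeline must measure it back.

# The synthetic generator

`generatorConfig()` holds every default. The signal chain it emulates:

* **Stimulus protocol** (`makeProtocol`): forward gratings at 3, 10, 30
  mm/s (5 s motion, 5 s static pauses), reverse/left/right gratings at 10
  mm/s, whole- and half-field windmills rotating at 0.2 Hz with sinusoidal
  velocity, and whole-field luminance flashes; blank trials contain a
  static grating only. Defaults run 4 stimulus + 2 blank trials (~12 min),
  the order of magnitude of a repeated-protocol cell-attached session.
  Epoch ordering beyond the canonical content is a free choice.
* **Behavior** (`simulateBehavior`): bout onsets follow an inhomogeneous
  Poisson process, elevated during forward/lateral motion and spontaneous
  during reverse motion, static periods and blanks. Bout durations are
  0.2–0.6 s (an integer number of burst cycles), rest gaps 1–5 s. Within a
  bout the VR trace bursts at 26.7 Hz with a 40% duty cycle; a per-bout
  vigor factor (CV 0.3) scales burst amplitude and all vigor-graded rates.
  Eye traces are low-pass-filtered copies of the windmill velocity with
  per-trial gain jitter (CV 0.3) and slow drift.
* **Purkinje cells** (`simulatePurkinje`): CS are a thinned inhomogeneous
  Poisson process with a 2-ms absolute refractory period. Because an
  absolute dead time depresses the observed rate by a factor
  1/(1 + lambda tau_r), intensities are dead-time corrected
  (lambda' = r/(1 - r tau_r)) so the **observed** rate equals the planted
  rate — this is what makes the rate-recovery contract exact. Phenotype
  intensity profiles: motion-onset cells add a 500-ms window at
  preferred-direction motion onsets integrating to 1.2 spikes; rotational
  cells multiply baseline (0.77 Hz) by 4.4 during preferred-direction
  rotation, drop to 0.32 Hz during non-preferred rotation and to 37% of
  baseline for 1 s after the epoch; luminance cells fire one spike with
  probability 0.80 at a fixed per-cell latency (150–400 ms, 5-ms jitter)
  after their preferred transition; motor cells elevate in-bout intensity
  so that a CS occurs on 38% of bouts. SS fire at 7.6 Hz scaled
  multiplicatively by instantaneous vigor so the mean in-bout rate is
  14.5 Hz. An optional post-CS multiplicative gain window (default 50 ms)
  models CS-driven pauses or facilitation; it is off by default so rate
  recovery is unconfounded.
* **Granule cells** (`simulateGranule`): 1.3 Hz at rest, 25.7 Hz in-bout,
  optionally phase-locked to the VR burst cycle (sinusoidal intensity
  modulation, depth 0.8) so the in-bout autocorrelation peaks at the cycle
  period.
* **Calcium** (`simulateCalcium`): dF/F is the CS and SS delta trains
  convolved with a single-exponential kernel (tau = 1.6 s) plus Gaussian
  noise. The CS/SS amplitude ratio is derived from the target CS share of
  the signal (78.4%) via Campbell's theorem — for Poisson trains the
  component SD is amplitude × sqrt(rate × ∫k²), and the kernel factor
  cancels — at the default paired-recording rates (0.5 Hz CS, 10 Hz SS).
* **Volumes** (`simulateNucleiVolume`): 433 spherical-Gaussian blobs
  (sigma 2 voxels) at non-overlapping random centers (minimum separation
  4 sigma) in a 128×128×48 volume, SNR 8.
* **Morphologies** (`simulateMorphology`): anisotropic Gaussian clouds
  whose planted axis variances give any requested PC3/PC2 ratio.

What the generator does **not** emulate: bursty non-Poisson CS statistics,
electrode drift and waveform overlap, eye saccades, imaging motion
artifacts and neuropil contamination, optical PSF structure. Passing the
recovery tests therefore demonstrates correctness of the analysis chain,
not robustness to every artifact of real data.

# Spike extraction

Cell-attached traces are high-pass filtered (first-order, zero-phase,
3 Hz within the conventional 1–10 Hz range) and events are contiguous
supra-threshold excursions; one event per excursion (timed at the peak)
avoids double-counting multiphasic waveforms. Excursions above the CS
threshold are complex spikes; the rest are simple spikes, except within
the 2.5-ms post-CS blanking window that prevents the CS waveform from
recrossing the SS threshold. Thresholds are set manually in practice; for
reproducible automation the package initializes them from the data (spike
floor at 4 MAD of the filtered trace; CS/SS boundary by an Otsu split of
excursion peak amplitudes). Thresholding is applied to signed positive
excursions by default, with `rectify = TRUE` available.

Trains become rates by convolution with a unit-area 20-ms boxcar
(`rateFromTrain`), so rate integrals equal spike counts. Baseline rates
come from blank trials when present, else from the 2-s pre-stimulus window
of each trial.

# Behavior

The VR envelope is a centered rolling SD. Its window is not a standard
value; the package uses 10 ms — short enough to resolve the ~27-Hz burst
cycle after binarization, long enough to smooth single spikes (tail-trace
vigor uses the conventional 50 ms, median-filtered over 200 ms to carry
vigor across the whole bout). Supra-threshold runs separated by **less
than** 100 ms belong to one bout; a gap of exactly 100 ms starts a new
bout (documented boundary convention). The default binarization threshold
is 3× the envelope median, a rest-dominated robust scale standing in for
the per-recording manual setting.

Swim frequency is the reciprocal lag of the first significant positive
peak of the pooled in-bout autocorrelation of the binarized envelope.
"Significant" is defined against a within-bout permutation null (95%
pointwise band, 50–100 shuffles); the peak lag is refined by parabolic
interpolation to beat the lag quantum at 1 kHz. Single isolated bursts are
flagged undefined.

The twelve eye channels are one consistent reading of "position and
velocity per eye in different directions": per eye, signed position and
velocity plus their positive and negative rectifications.

# Design matrices and encoding models

The canonical electrophysiology design has 24 columns: 4 motion-onset
windows (500 ms from onset), 4 motion-duration boxcars, graded grating
speed, rectified CW/CCW whole-field windmill velocities, 2 half-field
velocities, windmill direction-change impulses, luminance-transition
onset windows, ambient luminance, and 7 swim columns (onset, offset,
duration, vigor, and three derived timing variants). CS analyses drop two
timing variants (22 columns). Luminance transitions use 500-ms onset
windows rather than single-sample impulses because luminance-driven CS
arrive at per-cell latencies of 150–400 ms, which an impulse regressor
cannot capture; the onset-window construction used for motion covers
them. Imaging-mode regressors omit the onset windows and are convolved
with the GCaMP kernel (exact recursive exponential filter) and
renormalized to unit maximum; spiking-mode regressors are smoothed with
the same 20-ms boxcar as the rates.

Encoding fits: `fitOLS` (z-scored design; pseudoinverse with a flag under
rank deficiency) and `fitElasticNet`, the package's own cyclic coordinate
descent on

$$\min_{\beta_0,\beta} \frac{1}{2N}\sum_i (y_i-\beta_0-x_i^T\beta)^2 +
\lambda \sum_j \Big[\tfrac{1-\alpha}{2}\beta_j^2 + \alpha|\beta_j|\Big],$$

intercept unpenalized, convergence at relative objective change below
1e-8. Tests verify it against a dense grid search on all systems with up
to three regressors and against an independent library implementation.

Two conventions deserve explanation:

* **Lambda scaling.** The conventional values (alpha 0.2; lambda 0.9 for
  CS, 0.8 for SS) assume the response is a firing rate in Hz with a
  z-scored design. If the response is also z-scored, those lambdas exceed
  the largest attainable covariance of a 20-ms-filtered spike rate with
  any regressor and every coefficient collapses to zero; on rate responses
  in Hz the same values give the intended modest sparsification. The
  package therefore fits spiking responses unscaled (`standardizeY =
  FALSE` in the pipeline) and documents lambda as a rate-scale parameter.
* **Classification.** A cell's phenotype label is the category of its
  largest normalized weight, with per-direction onset regressors collapsed
  to `motion_onset`, rotation regressors to `rotational_velocity`,
  luminance transitions to `luminance`, and swim/eye to `motor`. Weight
  heatmaps of this kind are conventionally built from least-squares
  weights; the pipeline classifies from the sparse elastic-net fit when it
  retains coefficients and falls back to the OLS weights when the penalty
  removes everything (weakly driven cells on short sessions). Ties across
  categories break by summed category weight, then a fixed category
  order, and are flagged ambiguous.

Category fractions are sums of normalized absolute coefficients. The
calcium decomposition regresses dF/F on kernel-convolved CS and SS trains
and weights contributions as |beta| × SD(regressor) — on z-scored designs
this coincides with plain |beta| shares.

# Spike interactions

CS-triggered SS histograms use 10-ms bins over ±300 ms, normalized to the
mean per-bin count in the 100 ms preceding each trigger; cells with fewer
than ten triggers are excluded. Context splits assign each CS to motor
(inside a bout) or non-motor, and to sensory subsets by the full extent of
the containing epoch. The Ljung-Box Q-test runs on 5-ms-binned,
concatenated in-bout counts with 20 lags (both bin and lag count are
package conventions). The direction selectivity index defaults to the
preferred-versus-opposite contrast (R_pref − R_opp)/(R_pref + R_opp);
a vector-sum variant is available because the printed 0.2–0.9 range does
not disambiguate the formula.

# Population analysis

`pcaKmeans` clusters per-ROI correlation (or coefficient) vectors in the
space of the first 10 principal components with k-means (k = 10, 50
restarts, fixed seed). The anatomical clustering index compares, per fish,
the mean distance from a cluster ROI to a random same-fish ROI against the
mean within-cluster distance; the expectation of the random draw is
computed exactly (mean over all other ROIs), with a Monte-Carlo option.
The stereotypy index compares cross-fish other-cluster distances to
cross-fish same-cluster distances. Both average per fish and then across
fish (the ROI-weighted alternative is not used; the choice is flagged in
the accessors' documentation), both equal 1 at chance, and both are
invariant to global coordinate scaling.

# Anatomy

`countNuclei` computes zero-normalized cross-correlation with a spherical
Gaussian template via FFT (template wrapped to the origin; margins where
the window leaves the volume are discarded), then greedy non-maximum
suppression at 3 sigma. The default score threshold 0.3 sits between the
noise-only score ceiling (~0.1 for the default template size) and the
score of blobs at the packing limit (~0.5), replacing the manual
false-positive curation of practice with a reproducible rule. `planarity`
is the PC3/PC2 **eigenvalue** (variance) ratio by default; the
singular-value convention is available via `type = "sd"` since the ratio
definition is ambiguous in common usage.

# Numerical choices and degenerate inputs

* Rolling statistics shrink to the valid range at edges; boxcar smoothing
  zero-pads (events within half a window of an edge lose mass).
* Impulse regressors land on the nearest sample; all module clocks are
  seconds.
* Zero-variance design columns are kept at zero and excluded from
  coordinate descent; all-zero fits classify as "unclassified".
* Degenerate decompositions (one spike type absent) return a flagged
  100/0 split; zero-variance voxels get r = 0 with a flag; singleton or
  single-fish clusters yield NA indices.
* Determinism: every simulate* entry point derives its RNG stream from
  the config seed (restoring the caller's RNG state), so identical
  configs give bit-identical sessions and `runPipeline` is idempotent.

# Problem sizes

Defaults were chosen so a full desk-scale reproduction (one 61-cell
session, 30 behavioral sessions for the swim-frequency estimate, a
433-nucleus volume, 8 paired calcium recordings, 500 null simulations for
test calibration) completes in minutes on one CPU. Session bundles are
written as plain-text directories (CSV/YAML; TIFF for volumes, SWC for
morphologies).

# Known limitations

* Poisson spiking with dead time is the minimal generative model
  consistent with reported rates; real CS/SS interval statistics are
  richer.
* The canonical 24-regressor list is a declared convention; alternative
  compositions are configurable but untested against real data.
* The elastic-net lambda convention is tied to rate-scale responses;
  z-scored responses need proportionally smaller lambdas.
* Cross-fish coordinates are assumed pre-registered; no morphing or
  registration is performed.
* At high rates (≥ ~26 Hz) the dead-time correction is first-order; the
  residual bias is below 1% at the default granule in-bout rate.
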