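# zebellum

Sensorimotor encoding analysis of larval zebrafish cerebellar recordings:
from raw cell-attached electrophysiology, ventral-root (fictive swim) and
calcium traces to feature-encoding models, complex spike phenotype
classification, spike-interaction statistics, population clustering, and
3D nucleus counting — with a synthetic-data generator that makes every
stage verifiable by parameter recovery.

## Who this is for

Systems neuroscientists analyzing paired sensory/motor/electrophysiology
(or imaging) experiments in the cerebellum — in particular Purkinje cell
recordings where **complex spikes (CS)**, driven by climbing fibers at
well under ~1 Hz, and **simple spikes (SS)**, modulated by granule-cell
input at tens of Hz, must be separated, related to stimulus and behavior,
and mapped across the population.

## The model at the core

Each cell's activity (20-ms-boxcar firing rate, or dF/F for imaging) is
regressed on a design matrix of stimulus and motor features
$x_t$ — motion-onset windows, motion duration and speed, rotational
(windmill) velocities, luminance, swim onset/offset/duration/vigor, eye
kinematics — using elastic-net-penalized least squares:

$$\min_{\beta_0,\beta}\; \frac{1}{2N}\sum_{t=1}^{N}
\left(y_t-\beta_0-x_t^{\top}\beta\right)^2
+\lambda\sum_j\left[\frac{1-\alpha}{2}\beta_j^2+\alpha|\beta_j|\right]$$

with $\alpha = 0.2$ (modest sparsification, near ridge) and
$\lambda = 0.9$ (CS) or $0.8$ (SS) on rate-scale responses. For imaging,
regressors are first convolved with a GCaMP6s kernel
$k(t)=e^{-t/\tau}$, $\tau = 1.6$ s. A cell's phenotype
(motion-onset / rotational-velocity / luminance / motor) is the category
of its largest normalized weight $|\beta_j|/\sum_k|\beta_k|$. Around this
sit the standard stages: amplitude-threshold CS/SS sorting with 2.5-ms
post-CS blanking; bout detection by a moving-SD envelope with the
100-ms merge rule; swim frequency from the binarized in-bout
autocorrelation; CS-triggered SS histograms normalized to the preceding
100 ms; PCA + k-means functional clustering with anatomical-clustering
and stereotypy indices; and nucleus counting by normalized
cross-correlation with a 3D spherical-Gaussian template.

The synthetic generator (`generatorConfig()`, `simulateSession()`)
produces stimulus protocols, bursty fictive behavior (26.7-Hz intra-bout
cycles), phenotype-specific spike trains, calcium, volumes and
morphologies with all planted parameters recorded as ground truth.

## Worked example

```r
library(zebellum)

cfg <- generatorConfig(seed = 7,
                       phenotypeMix = c(motion_onset = 2L,
                                        rotational_velocity = 2L,
                                        luminance = 1L, motor = 1L))
run <- runPipeline(runConfig(seed = 7, generator = cfg))
run$session
#> SyntheticSession: 720 s, 142 bouts, 6 cells (seed 7)
sprintf("Detected %d bouts; fictive swim frequency %.1f Hz",
        nBouts(run$bouts), run$swimFreq$frequency)
#> "Detected 145 bouts; fictive swim frequency 26.6 Hz"
reportSummary(run)[, c("cellId", "planted", "label", "recovered")]
#>                     cellId             planted               label recovered
#> 1        pc01_motion_onset        motion_onset        motion_onset      TRUE
#> 2        pc02_motion_onset        motion_onset        motion_onset      TRUE
#> 3 pc03_rotational_velocity rotational_velocity rotational_velocity      TRUE
#> 4 pc04_rotational_velocity rotational_velocity rotational_velocity      TRUE
#> 5           pc05_luminance           luminance               motor     FALSE
#> 6               pc06_motor               motor               motor      TRUE
```

The pipeline generated a 12-minute synthetic session, re-detected the
planted swim bouts from the ventral-root envelope (145 detected vs 142
planted; the extras are brief noise crossings), recovered the planted
26.7-Hz burst cycle from the in-bout autocorrelation, fitted encoding
models to every cell, and labelled five of six cells with their planted
phenotype — the missed luminance cell is weakly driven (0.28 Hz baseline,
one spike per preferred flash), the hard case at this session length.
Larger populations at defaults recover ~95% of labels (see the methods
vignette, `vignettes/zebellum-methods.Rmd`).

Individual stages are plain functions: `detectSpikes()`,
`envelopeSD()`/`detectBouts()`/`swimFrequency()`, `ephysDesign()`,
`fitElasticNet()`/`classifyPhenotype()`, `csTriggeredSS()`,
`pcaKmeans()`/`anatomicalClusteringIndex()`, `countNuclei()`,
`planarity()`.

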