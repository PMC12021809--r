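---
title: "Methods: fibrosis synthesis, AF simulation and ablation-outcome prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fibrosis synthesis, AF simulation and ablation-outcome prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`fibrotwin` implements, at desktop scale, an in-silico pipeline for studying
atrial fibrillation (AF) ablation on 2D fibrosis maps: generative synthesis
of late-gadolinium-enhancement (LGE)-like fibrosis distributions with a
denoising diffusion probabilistic model (DDPM), spatial-statistics quality
control, image-driven tissue remodeling, monodomain AF simulation with a
modified Courtemanche atrial myocyte model, feature extraction (dominant
frequency and phase-singularity density), and a Siamese two-head classifier
with outer-arithmetic fusion that predicts termination after four ablation
strategies. This vignette records the models, the tunable parameters and
the design decisions, in the package's own words.

## Fibrosis maps

All maps live on a 96×96 grid representing the unfolded
universal-atrial-coordinate view of one atrium, in image intensity ratio
(IIR) units — LGE-MRI voxel intensity over blood-pool intensity, clipped to
[0, 2]. Three sources matter:

* **Noise baselines** (`generate_noise_map()`): i.i.d. standard-normal
  pixels, min–max rescaled so every map spans exactly [0.25, 1.75] IIR.
  These are the spatially unstructured reference against which structure
  statistics are judged; their ensemble grand mean is ≈ 1.0 IIR.
* **LGE-like fixtures** (`generate_lge_like_fixture()`): a Gaussian random
  field (white noise smoothed with σ = correlation length / 2, default
  correlation length 8 px), standardized by the theoretical marginal SD of
  the smoothed field and warped through a Gaussian copula onto a shifted
  gamma marginal (shape 4). Defaults are calibrated once to the published
  summary statistics of clinical atrial LGE-MRI: per-map mean ≈ 1.1 IIR,
  pixel spread ≈ 0.25, suprathreshold (> 1.22 IIR) cluster fraction
  ≈ 0.2–0.3, and a filter pass rate around 90%. Small per-map mean/spread
  jitters (SD 0.04 and log-SD 0.06) emulate patient-to-patient burden
  variation while keeping the entropy distribution near the reported
  0.8 ± 0.1. The standardization deliberately uses the *theoretical* SD, so
  correlation lengths far beyond the grid degrade gracefully to
  near-constant maps instead of amplifying residual noise.
* **Synthetic maps**: DDPM samples (below).

What the fixtures do *not* emulate: atrial anatomy (PV ostia, appendage),
scanner-specific noise, segmentation artifacts, or the left/right asymmetry
of real burden distributions. Tests passing on fixtures therefore establish
that the pipeline machinery is correct and calibrated — not that it has
been validated on clinical data.

## Spatial statistics and the quality filter

Both statistics are computed after Gaussian pre-smoothing. The
"kernel 3" smoothing is read as **σ = 3 px**: only heavy smoothing is
consistent with a lattice Moran's I of ≈ 0.98 on noise maps, since the
lag-1 autocorrelation of σ-smoothed white noise is exp(−1/(4σ²)) ≈ 0.97 at
σ = 3. Smoothing uses separable convolution with symmetric (reflective)
boundaries, which avoids edge darkening on 96-px maps.

**Normalized Shannon entropy** has three estimators
(`spatial_stats_config(se_mode = ...)`):

* `weighted_eq34` — the literal pixel-mass form
  $SE = -\tfrac{1}{\log_2(N_x N_y)} \sum_{ij} P_{ij}\log_2 P_{ij}$,
  $P_{ij} = S_{ij}/\sum S_{ij}$. Taken literally this yields SE ≈ 1 for
  *any* near-uniform image — including smoothed noise — so it cannot
  reproduce a low noise entropy; it is kept because it is the printed
  formula and is tested against a brute-force oracle.
* `histogram` — gray-level histogram entropy over [0, 2] IIR, normalized by
  the same $\log_2(N_x N_y)$.
* `binary_fraction` (default for the filter) — the binary entropy of the
  fraction of pixels above 1.22 IIR. This tracks fibrotic-cluster burden:
  smoothed noise has essentially no suprathreshold pixels (SE → 0) while
  structured maps with 20–30% burden score ≈ 0.7–0.9, matching the reported
  ordering and magnitudes.

Because the literal estimator scores near-uniform images *highest*, the
noise-below-fixture entropy ordering holds for the histogram and
binary-fraction modes and is *inverted* for `weighted_eq34`; the test suite
asserts exactly that.

The **quality filter** (`filter_by_entropy()`) rejects maps with SE ≤ 0.66
under the configured mode — the boundary value is rejected.

**Moran's I** uses row-normalized rook (4-neighbour) adjacency on the
(smoothed) pixel lattice, computed via neighbour sums so no n² weight
matrix is formed; an O(n²) brute-force version and `ape::Moran.I` serve as
oracles in the tests.

## Diffusion model

The forward process corrupts a map over $T$ steps,
$q(x_t\,|\,x_{t-1}) = N(\sqrt{1-\beta_t}\,x_{t-1},\ \beta_t I)$, with the
original linear schedule: $T = 1000$, $\beta$ from $10^{-4}$ to
$2\times10^{-2}$. Training regresses the injected noise
($\epsilon$-parameterization, MSE loss) at uniformly drawn timesteps; the
reverse step samples
$N(\mu_\theta, \beta_t I)$ with
$\mu_\theta = (x_t - \tfrac{\beta_t}{\sqrt{1-\bar\alpha_t}}\hat\epsilon)/\sqrt{\alpha_t}$
and no noise at $t = 1$. Maps are mapped linearly from [0, 2] IIR to
[−1, 1] and samples clipped back.

The denoiser is a 3-level U-Net with single-head self-attention at levels
2 and 3 and sinusoidal timestep embeddings injected as per-level channel
scale-and-shift (FiLM) conditioning — plain additive conditioning leaves
the network without the strongly t-dependent output gain that
ε-prediction requires, which shows up as a DC bias in the samples of
compact models. Widths default to (8, 16, 32): the package trains through its own
R autodiff engine on one CPU, and these widths train on ≤ 100 maps in
minutes while wider configurations (e.g. 64/128/256) remain constructible
via the `channels` argument. The published training profile (500 epochs,
Adam 2.5×10⁻⁵) is preserved as `ddpm_train_config(profile = "full")`; the
default desk profile is 60 epochs at 2×10⁻³.

The engine itself (`R/nn-autodiff.R`) is a tape-based reverse-mode
autodiff over dense arrays (convolution as shifted-slice matrix products,
batched attention, layer norm, Adam); its gradients are validated against
central finite differences through the complete U-Net graph.

## Tissue remodeling

Structural remodeling maps IIR to conductivity with left-closed bins:
[0, 0.9) → 0.40, [0.9, 1.4) → 0.31, [1.4, 1.6) → 0.28, [1.6, ∞) → 0.19 S/m
(the printed strict inequalities leave the boundaries unassigned; they join
the higher-fibrosis bin so the mapping is total and deterministic).

Ionic remodeling composes three multiplicative layers on the Courtemanche
maxima: baseline calibration (g_Na×2, g_K1×0.8), AF electrical remodeling
(g_to×0.5, g_Kur×0.5, g_CaL×0.3), and fibrotic electrophysiological
remodeling where IIR exceeds a threshold (g_K1×0.5, g_Na×0.6, g_CaL×0.5).
The fibrotic threshold is not stated by the calibration sources; the
package reuses the 1.22 IIR ablation-mask threshold for internal
consistency (configurable).

Ablation is non-conducting tissue. The LA mask always carries two PVI
ring annuli (unit-coordinate centers (0.2, 0.8) and (0.8, 0.8), radius
0.12, width 2 px — placement in the unfolded coordinates is a package
choice, configurable); strategies including LA or RA add the
suprathreshold (> 1.22 IIR) pixels of that atrium. The RA has no PVI
lesion, so the RA PVI channel is identically zero. Ring interiors remain
conducting but isolated.

## Electrophysiology

The monodomain equation is integrated on flat 2D sheets (one per atrium)
with no-flux boundaries, a 5-point Laplacian expressed as an edge graph,
and three interatrial bridge edges (configurable) standing in for the
interatrial connections of a 3D bilayer geometry. The full 21-variable
Courtemanche model supplies the ionic current; integration is operator
splitting with Rush–Larsen gate updates (voltage-indexed lookup tables of
gate steady states and time constants, 0.02 mV resolution, linear
interpolation) and forward Euler for voltage and concentrations. Nernst
potentials are refreshed on a 0.5 ms cadence since intracellular
concentrations drift slowly. The compiled solver is validated against an
independent adaptive-ODE (LSODA) integration of the same equations
(`courtemanche_derivs()`), and a diffusion step exceeding the explicit
stability bound is automatically subdivided or rejected.

The single free tissue parameter is the product χ of surface-to-volume
ratio and membrane capacitance (diffusivity = σ/χ): it is calibrated once
so that planar conduction velocity at 0.40 S/m equals 0.81 m/s on a
100-node, 0.25 mm strand paced at one end, with CV read from the
activation-time difference of two interior probes. CV measurements disable
fibrotic EP remodeling: the published conductivity–CV pairs are
structural-remodeling calibrations, and a 40% g_Na reduction would depress
CV far below them. Desk-scale defaults: reaction dt 0.02 ms (0.05 ms in the
smoke profiles), diffusion every 2–5 reaction steps, 1 ms trace sampling.

AF is initiated from four Archimedean spiral waves (two cores per atrium),
each node assigned phase φ = atan2(y−y_c, x−x_c) − kr to its nearest core
(k = 2π/40 px) and mapped onto a precomputed single-cell limit-cycle
trajectory (one paced AF-remodeled action-potential cycle at 250 ms). Core
placement is seeded-uniform within the interior and recorded per case. An
episode is **sustained** when the latest −40 mV upstroke anywhere occurs at
or after 60% of the episode; the −40 mV upstroke detector is the package's
reading of "electrical activity", which the sources do not pin down.

Simulated episodes default to 2 s (the 15 s protocol is retained in the
`full` profile); a deterministic quiescence early-exit skips dead time
after global repolarization.

## Features and labels

* **Dominant frequency**: per node, mean-removed Hann-windowed power
  spectrum; DF is the frequency of the maximal peak at ≤ 20 Hz, and
  quiescent nodes get DF = 0. Traces must cover two periods of the spectral
  floor (1 Hz by default; short desk-scale episodes raise the floor
  accordingly).
* **Phase singularities**: phase is the angle of the analytic signal
  (FFT-based Hilbert transform) of each node's mean-removed voltage; a
  singularity is a 2×2 plaquette whose wrapped phase circulation is ±2π.
  The detector is validated against an explicit loop-integral oracle.
* **PSD maps**: PS detections counted per pixel over all frames, smoothed
  with σ = 2 px; pre-smoothing counts conserve the total detection count.
* **Ground truth**: per conducting node the time of the last
  action-potential peak (local maximum above −40 mV) as a fraction of the
  episode; fractions averaged over both atria. Terminated ⇔ average ≤ 0.6
  (the 0–60% range is read as closed, so exactly 0.6 is terminated).
* **Feature stacks**: five channels per atrium in fixed order — PVI mask,
  PVI+fibrosis mask, PSD, DF, fibrosis — normalized to [0, 1] (masks
  binary, DF/20 Hz, PSD by its per-map maximum, IIR/2). Channel
  normalization is a package choice.

## Classifier

One shared-weight convolutional head (compact `densenet_like`, 3 dense
blocks, or `convnext_like`, 4 downsampling stages — both sized for
96×96×5 inputs on a CPU) maps each atrium to a 32-long latent. Fusion is
`concat`, `moab` (outer sum/product/difference/stabilized division stacked
as four 32×32 channels, reduced by a stride-2 convolution) or `foaa`
(bidirectional cross-attention whose score maps are the four outer
operations between learned Q and K projections, softmax over the key
dimension, attended values summed and added to the single-modality
features via skip connections, then a 1D convolution). All modes share the
48- and 30-wide fully connected layers, layer normalization, dropout and a
4-logit sigmoid output ordered (PVI, PVI+LA, PVI+RA, PVI+LA+RA). The outer
division is stabilized with ε = 10⁻⁶; softmax-over-keys is the package's
choice where the fusion literature leaves normalization open.

Training is summed binary cross-entropy with Adam, early stopping
(patience 20) on validation mean ROC-AUC. The published 4×10⁻⁷ learning
rate is preserved as the `full` profile but is impractically slow for the
small cohorts trained here; the desk default is 10⁻³, which reaches mean
AUC ≥ 0.95 on a separable synthetic cohort within tens of epochs. ROC-AUC
is the rank (Mann–Whitney) statistic, cross-checked against `pROC`;
grouped k-fold cross-validation keeps fibrosis-map pools disjoint across
folds.

## Cohort orchestration

`experiment_config()` fixes the whole study: cohort sizes per split
(train-real / train-comparison / validation / test), the comparison-split
source (noise, fixtures, or DDPM samples filtered by entropy), the 80/10/10
partition of the real-like map pool (maps may be reused within a split,
never across splits), episode and solver settings, and one global seed
from which every stage derives its own stream (`mix_seed()`), making
cohort manifests, simulations, features, labels and trained weights
reproducible byte-for-byte.

Two decisions the before/after design leaves open are fixed as: post-
ablation episodes **restart from the pre-ablation final state** with the
lesions applied (termination then means the standing wave pattern cannot
survive the lesion set), and non-sustained pre-ablation cases are **kept**
in the cohort with computed labels (a config switch excludes them).

Profiles: `smoke` — 10/10/5/5 cases, 2 s episodes, 48-px sheets at 2 mm
(≈ 9.6 cm domain), sized to complete end-to-end on one CPU within the
hour; `desk` — 40/40/10/10 cases, 64-px sheets at 1.5 mm; `full` —
400/400/100/100, 15 s, 192-px sheets at 0.5 mm, retained for cluster use.
The automated test suite runs a further-reduced smoke (10 cases, 0.8 s
episodes, 40-px sheets) and trains the neural components on 16–32-px
inputs and small schedules; these sizes are the package's desk-scale
choices and the properties under test are scale-free.

## Numerical notes and limitations

* The measured CVs at 0.31/0.28/0.19 S/m track the √σ law of the
  continuum monodomain equation within the ±10% acceptance band; the
  printed pairs came from a 3D finite-element mesh and sit a few percent
  above √σ scaling, so exact agreement is not attainable on any 1D strand.
* Coarse lattices (≥ 3 mm spacing) reach conduction block at the lowest
  conductivity bin; the smoke profiles stay at ≤ 2.4 mm.
* 2D sheets with three bridges preserve bi-atrial coupling only
  qualitatively; rotor statistics, wavelength and termination rates are
  not claimed to match 3D bilayer dynamics.
* Small smoke cohorts can yield single-class label columns; AUC for such
  a column is reported as `NA` and excluded from the mean with a warning.
* The headline full-cohort metrics of the original study (test ROC-AUC
  ≈ 0.95 and cohort percentage tables) require thousands of 15 s
  bilayer simulations and are out of scope at desk scale; nothing in this
  package asserts them.
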