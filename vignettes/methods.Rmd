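---
title: "Methods: growth-aware lung tumor segmentation and immune-evasion scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: growth-aware lung tumor segmentation and immune-evasion scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`mkunet` implements a growth-aware analysis chain for longitudinal lung CT:
multi-modal preprocessing of Hounsfield-unit (HU) volumes, tumor growth
kinetics via the log volume change rate (LVCR), a 3-D attention-gated
encoder–decoder segmentation network with clinical-metadata fusion,
segmentation metrics (Dice, IoU, HD95), shape radiomics (sphericity), and a
composite Immune Evasion Score (IES). A synthetic longitudinal phantom
generator with known ground truth makes every stage testable on a laptop
without any clinical data. This vignette records the models, the tunable
parameters, and the design decisions taken where the problem was genuinely
open.

# Multi-modal preprocessing

The network consumes a fixed 4-channel stack per volume:

1. **Raw HU passthrough** — untouched calibrated intensities.
2. **Canny edge map** — intensities min-max rescaled to [0, 1], Gaussian
   smoothing at `sigma = 1.5` pixels, Sobel gradients, non-maximum
   suppression and hysteresis with `low = 0.1`, `high = 0.2`. Canny is a 2-D
   operator; with 3 mm slices against 0.6 mm in-plane resolution the
   meaningful edge signal is in-plane, so the detector runs per axial slice
   and the maps are restacked.
3. **Gaussian denoising** — separable 3-D truncated Gaussian, kernel 3,
   `sigma = 0.8` voxels, replicate padding. The separable normalized kernels
   multiply to the normalized 3-D kernel, so a unit impulse integrates to 1
   and constants are fixed points.
4. **Windowed GLCM contrast** — intensities linearly rescaled to [0, 255]
   and quantized to 32 gray levels; within a sliding 5×5×5 window a
   symmetric, normalized gray-level co-occurrence matrix over the three unit
   axis offsets is summarized by its contrast
   $\sum_{i,j} P(i,j)\,(i-j)^2$, averaged over offsets, with
   edge-replication padding at borders. The co-occurrence matrix is never
   materialized: for the contrast statistic,
   $\sum_{i,j} P(i,j)(i-j)^2$ equals the mean squared level difference over
   co-occurring pairs, which cumulative-sum box filters compute exactly, at
   a small constant cost per voxel. Offsets, level count and symmetry follow
   standard Haralick practice; the unit tests verify the identity against an
   explicitly counted co-occurrence table.

**Adaptive windowing.** Background suppression thresholds each voxel against
statistics of the annotated tumor: with tumor mean $\mu$ and standard
deviation $\sigma$, the default *lower-bound* mode masks voxels below
$\mu - k\sigma$ (default $k = 1.5$), replacing them with the air floor
(−1024 HU). A *literal* mode thresholding at $\mu + k\sigma$ is also
provided; on approximately Gaussian tumor intensities it retains only the
$1-\Phi(1.5) \approx 6.7\%$ upper tail of tumor voxels, which defeats the
purpose of preserving tumor texture — the package therefore defaults to the
lower-bound form and records the mode, threshold and statistics in the
output metadata so no run is ambiguous.

**Augmentation** applies one sampled in-plane rotation (±10°), isotropic
scale (0.9–1.1), translation (±5 voxels) and additive Gaussian HU noise
(sd 10) per call, identical across channels (trilinear) and mask (nearest
neighbor), fully determined by one seed. Rotation is in-plane for the same
anisotropy reason as the edge channel. Noise is added only to the HU-valued
channels: the edge map is binary and the contrast map is a derived texture
statistic.

# Growth kinetics: LVCR

For a series of segmented tumor volumes $V_i$ (cm³) at times $t_i$ (days,
baseline $t_1 = 0$), the log volume change rate is the weighted
least-squares slope

$$\mathrm{LVCR} \;=\; \frac{\sum_i w_i\,(\ln V_i - \overline{\ln V}_w)(t_i - \bar t_w)}
                           {\sum_i w_i\,(t_i - \bar t_w)^2}\quad[1/\text{day}],$$

with *weighted* centering means: this is the standard weighted LS estimator,
reduces exactly to OLS under uniform weights, and is invariant to rescaling
either the weights or the volumes by positive constants. Three weighting
schemes are provided: uniform (default, most reproducible), time-interval
($w_i = t_i - t_{i-1}$; the undefined first weight is set to the mean of the
remaining interval weights, and this is logged), and inverse-variance
($w_i = 1/\sigma_i^2$, requiring per-scan volume uncertainties, for which no
default measurement procedure exists — it is available but never assumed).
Tumors are called *high-growth* when LVCR strictly exceeds 0.15/day.
Volumes come from mask voxel counts times voxel volume, not fitted
ellipsoids.

# The segmentation network

A 4-level 3-D U-Net-style encoder–decoder, built from first principles in
R (im2col convolutions in C++ plus BLAS matrix products, hand-written
backward passes verified against finite differences):

* encoder channels 32 → 64 → 128 → 256 (doubling per level), two 3×3×3
  convolutions + ReLU per level, 2× max pooling; four downsamplings in
  total, so patch dims must be divisible by 16;
* a bottleneck that widens to 512 and projects back to a 256-channel map;
* **clinical fusion**: the 6-D clinical vector (age/100; gender; smoking
  history; grade rank/3; stage rank/4; LVCR min-max normalized over
  [−0.05, 0.30] 1/day, clipped) is broadcast across the bottleneck grid as
  six constant channels, concatenated, and fused by a 1×1×1 convolution
  back to 256 channels;
* **attention gates** on every skip connection: a single linear map over the
  concatenated encoder and (upsampled) decoder features plus bias, squashed
  by a sigmoid into one weight per spatial location,
  $\alpha = \sigma(W_\theta[f_{enc}, f_{dec}] + b_\theta)$, multiplying the
  encoder features. In **IAAG** mode the normalized LVCR joins the
  concatenation as one constant channel, so attention strength can depend on
  growth kinetics; with a zero LVCR weight the gate is exactly the plain
  gate. One flag switches all four gates together;
* decoder upsampling by zero-insertion followed by a 3×3×3 convolution
  (a fractionally-strided convolution), concatenation with the gated skip,
  two convolutions; a final 1×1×1 convolution + sigmoid yields the
  voxel-wise tumor probability.

The default schedule has ≈20.6 M trainable parameters. No normalization
layers are used: desk-scale experiments train stably with He initialization
on [0, 1]-normalized inputs, and omitting them keeps the hand-written
backward pass small and exactly testable. All parameter initialization,
data ordering and augmentation derive from explicit seeds; identical seeds
give bit-identical histories.

**Training** minimizes the hybrid loss
$\lambda_1\,\mathrm{DiceLoss} + \lambda_2\,\mathrm{BCE}$ with
$\lambda_1 = 0.6$, $\lambda_2 = 0.4$, by Adam at learning rate $10^{-4}$,
batch size 2, 150 epochs by default — all overridable, and desk-scale runs
use far smaller budgets (see below). The soft Dice loss uses smoothing
$\epsilon = 1$; the evaluation Dice uses exact counts ($\epsilon = 0$).
Inference crops to a tumor ROI box, pads to divisibility, and re-embeds the
thresholded (default 0.5) mask into the full grid.

# Metrics

Dice $2|A\cap B|/(|A|+|B|)$ and IoU $|A\cap B|/|A\cup B|$ use exact voxel
counts and satisfy $\mathrm{Dice} = 2\,\mathrm{IoU}/(1+\mathrm{IoU})$
per case. HD95 extracts surface voxels (foreground with a background
6-neighbor; outside the array counts as background), computes directed
nearest-surface distances both ways in physical mm, and takes the 95th
percentile (linear interpolation) of the **pooled** bidirectional
distances. Pooling makes the metric symmetric; whether a given report pools
or takes the maximum of directed percentiles is a genuine dialect choice,
so the convention is stamped into every report. Cases with an empty mask
have undefined HD95 and are excluded from aggregates with a logged count;
both-empty overlap metrics return 1 with a degenerate flag. Aggregation is
overall and stratified by LVCR (strict 0.15/day).

# Shape radiomics and the IES

**Sphericity** is $\pi^{1/3}(6V)^{2/3}/A$ with $V$ from voxel counts (mm³)
and $A$ from an iso-surface mesh at level 0.5. The mesh is built by
marching tetrahedra (each cell split into six tetrahedra sharing a main
diagonal — no case tables, every case derivable by hand) on the occupancy
field smoothed by a small Gaussian (σ = 1 voxel, zero-padded so surfaces
close). Meshing the raw binary field staircases oblique surfaces and
overestimates area by up to tens of percent, breaking the sphericity = 1
calibration for balls; sub-voxel smoothing restores an accurate surface
(voxelized balls measure 1.00 ± 0.01 across radii 8–20 and resolutions).
The cost is edge rounding of genuinely sharp creases at the σ scale, an
$O(\sigma/\text{side})$ relative error that vanishes with resolution — the
cube calibration test therefore runs at side 120 voxels, where the estimate
is within 0.02 of $(\pi/6)^{1/3}$. Tumor masks are blob-like, so the
ball-calibrated regime is the operative one.

**IES** combines growth, shape irregularity and immune-marker burden:

$$\mathrm{IES} = 0.6\cdot\mathrm{LVCR} + 0.3\,(1-\mathrm{Sphericity})
  + 0.1\cdot\mathrm{PDL1^{+}AreaRatio},$$

with weights taken as fixed published constants (they derive from a
multivariate Cox model on a clinical cohort; re-deriving them is out of
scope). The three terms mix units, so by default the LVCR term enters
through the same min-max normalization as the clinical vector
([−0.05, 0.30] 1/day → [0, 1]); a raw-slope mode exists and every result
records which mode produced it. The PD-L1⁺ region is an input mask (e.g.
registered pathology); when absent the ratio is 0 with a missing flag —
the package never infers PD-L1 status from imaging. Sphericity is computed
on the **latest** mask of the series (the score is meant to reflect the
current phenotype); an IES stratum cutoff, when needed, defaults to the
cohort median and is logged.

# The phantom generator

Phantoms emulate the cohort structure the methods assume: ≥ 2 scans per
patient with known acquisition times, a tumor mask per scan, and clinical
metadata. The tumor is a ball (optional low-HU necrotic core; optional
conical spiculations on seeded random directions, which keep their full
base width out to the ball surface and taper beyond it so that voxelization
cannot erase them) whose radius is scaled so
mask volume follows $V_0 e^{g t}$ exactly for a chosen true slope $g$;
masks are the exact generating shapes, and volumes add Gaussian intensity
noise over a plausible HU palette (lung background −800 ± 50, tumor
40 ± 15, necrosis −20 ± 10). Default desk-scale grid 96×96×48 at 1 mm
(cohort writer: 48×48×32); scan times default to (0, 30, 60) days for
slow-growing phantoms and (0, 5, 10) in the cohort writer so that
fast-growing tumors (up to 0.25/day, deliberately spanning both sides of
the 0.15/day stratification threshold) stay inside the grid — a tumor
growing at 0.25/day for 60 days would multiply its volume by $e^{15}$,
which no fixed grid (or patient) accommodates.

What the phantoms do *not* emulate: reconstruction-kernel texture, beam
hardening, partial-volume effects at 3 mm slices, pleural/vascular
attachment, or inter-observer contour variability. Passing phantom tests
therefore demonstrates correctness of the computational chain (geometry,
kinetics, optimization), not clinical-grade segmentation accuracy.

# Desk-scale budgets and numerical choices

The test suite trains real models but at reduced size: 32³ crops,
base width 4 (channels 4–8–16–32), learning rate 1–3·10⁻³ (the default
10⁻⁴ is tuned for 150-epoch runs and moves too slowly in a 120-step
budget), ≤ 300 gradient steps. An overfit check drives one phantom patch to
Dice ≥ 0.9; a generalization check trains on 8 phantoms and validates on 2
held out (30 epochs). Further choices: BCE probabilities clipped at 10⁻⁷;
predictions thresholded strictly above 0.5; maxpool backward routes
gradients to the argmax (first maximum on ties); splits use
largest-remainder rounding with the remainder assigned to training (420
cases at 71.4/14.3/14.3% give exactly 300/60/60); all validation errors are
typed conditions rather than silent coercions.

# Known limitations

* DICOM series are not read (no DICOM parser among the package's
  dependencies); volumes enter as NIfTI with slope/intercept applied.
* The network trains single-threaded on CPU; the default 28-million-class
  configuration is practical for inference and architecture checks, while
  training at clinical scale would require GPU-class hardware.
* σ for inverse-variance LVCR weighting has no default estimator.
* Sphericity of masks only a few voxels across is biased upward by the
  sub-voxel smoothing; radiomics on sub-centimeter masks should be read
  with that caveat.
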