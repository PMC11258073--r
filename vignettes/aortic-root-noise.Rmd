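---
title: "Automatic noise and SNR measurement in the aortic root: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic noise and SNR measurement in the aortic root}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Image noise and vascular attenuation are two of the main determinants of
diagnostic image quality in coronary CT angiography (CCTA). Both are
conventionally quantified by placing a region of interest (ROI) in the
contrast-filled aortic root at the level of the left main (LM) coronary
ostium: the mean attenuation in Hounsfield units (HU) is the signal, the
standard deviation of the HU values (HUsd) is the noise, and their
quotient is the signal-to-noise ratio (SNR, dimensionless). Manual ROI
placement is reader-dependent and does not scale to cohorts of hundreds
or thousands of studies; `rootnoise` automates the whole chain.

The pipeline is:

1. **Resample** the study to a working grid of (0.9, 0.66, 0.66) mm per
   voxel (z, y, x). We assign the coarsest step, 0.9 mm, to the axial
   axis, which is the coarsest axis of typical CT reconstructions; the
   assignment is configurable.
2. **Segment** the aortic root, the LM and the proximal right coronary
   artery (RCA) with a 3D U-Net.
3. **Postprocess** each class: keep the largest 26-connected component,
   fill enclosed cavities.
4. **Locate the LM ostium**: dilate the LM mask by one voxel within each
   axial plane (3x3 structuring element, deliberately no through-slice
   dilation) and intersect with the aorta mask. The median axial index of
   these contact voxels is the measurement center slice; half-integer
   medians round toward the lower index. If the dilated LM never touches
   the aorta — as happens with rare anomalies such as an LM originating
   from the RCA — the study is recorded as a `ContactNotFound` failure
   rather than dropped or crashed on.
5. **Build the measurement zone**: the seven axial slices centered on the
   contact slice (three above, three below), with each aorta
   cross-section radially shrunk by one third of its equivalent-circle
   radius so the zone stays clear of the vessel wall and partial-volume
   voxels. Slices clipped at a volume edge are dropped with a warning
   recorded in provenance.
6. **Measure**: attenuation = mean HU over the zone, noise = sample
   standard deviation (n − 1 denominator), SNR = attenuation / noise
   (reported as undefined, never infinite, when the variance is zero).

A manual-comparator operation, `measure_manual_roi()`, reproduces what a
reader does: a single-slice circular ROI of 15 mm diameter at the root
center at the LM level.

## Geometric conventions and numerical choices

**Equivalent radius.** Aorta cross-sections are not exactly circular, so
"shrink by 1/3 of the radius" needs a radius definition. We use the
equivalent-circle radius `r = sqrt(area / pi)` computed from the slice
area in mm². The alternative — the maximum inscribed radius — is
unstable on noisy segmentations, where a single mislabelled boundary
voxel can change it substantially.

**Distance-based shrinking.** Shrinking is implemented as a threshold on
the Euclidean distance transform in millimetres (Felzenszwalb's exact
separable algorithm with anisotropic spacing), not as iterated voxel
erosion, which would be anisotropic on a (0.66, 0.66) in-plane grid and
quantized to whole voxels. The distance to the nearest background voxel
*center* overestimates the distance to the mask boundary by about half a
voxel, so we subtract half the mean in-plane spacing; on a disc of radius
30 voxels the retained-area fraction is then within 0.02 of the analytic
(2/3)² = 4/9.

**Sample SD.** Noise uses the n − 1 denominator. At the zone sizes the
pipeline produces (roughly 4–7 thousand voxels) the difference from the
population formula is far below measurement noise, but fixing it makes
method comparisons well-defined.

**Ties and degenerate inputs.** Argmax ties during inference go to the
lowest class code. Equal-size connected components keep the one whose
minimum (z, y, x) index is lexicographically smallest. Empty masks stay
empty through postprocessing; an all-empty zone raises a typed
`zone_empty` error. Voxel indices are 1-based throughout, matching R's
native convention, with axis order (z, y, x) and voxel-center
coordinates.

## The segmentation network and its training schedule

No deep-learning framework is available to R in this project's
dependency set, so the package implements a compact 3D U-Net directly:
im2col-based 3x3x3 convolutions (C++ kernels + BLAS products), instance
normalization, ReLU, 2x2x2 max pooling, nearest-neighbour upsampling and
skip connections, with exact hand-derived backward passes (verified
against finite differences in the test suite). This keeps training fully
deterministic given a seed, which the reproducibility tests rely on.

The training schedule is: cross-entropy loss with an ignore label, Nadam
optimizer, initial learning rate 1e-4 halved when the validation loss
has not strictly decreased for 5 epochs, early stop after 10 epochs
without decrease, L2 weight regularization 1e-3 on convolution weights,
and dropout 0.5 before the last and second-to-last convolution layers.
An epoch is a fixed number of sampled-patch iterations (20,000 at full
scale). Periodically (every 500 epochs at full scale) the model is run
over the entire training set and per-voxel cross-entropy re-weights
patch sampling: cases are drawn proportional to their mean loss and
patch centers within a case proportional to voxel loss — the simplest
mechanism that samples high-loss areas at a higher rate. Before the
first mining pass, half of all patches are centered on a random
labelled voxel so the small arteries are seen at all. The checkpoint
with the highest aorta-class validation Dice is kept; aorta Dice (rather
than the class mean) is the criterion because the aorta segmentation is
what the measurement zone is built from.

**Label preprocessing.** Annotated artery voxels far from the aorta
(default cutoff 20 mm, configurable) and the one-voxel inner and outer
boundary shells of every class are set to an ignore label: edge voxels
are neither well-defined nor precise, and distal artery segments are
irrelevant to locating the ostium. Ignored voxels contribute exactly
zero loss and zero gradient.

**Desk-scale defaults.** The toy preset trains a 3-level, base-width-8
net on (16, 24, 24) patches, batch 2, 200 iterations per epoch, mining
every 5 epochs, capped at 2 epochs, with the initial learning rate
raised to 1e-3. Depth, width, patch and batch size are nowhere
prescribed by the measurement protocol; these values are the smallest
configuration that reliably segments the synthetic phantoms on a single
CPU in minutes (held-out aorta Dice ≈ 0.93–0.95 on phantoms). The
full-scale defaults (4 levels, width 32, 20,000 iterations, patience-
driven stopping) are retained in `training_config()` but are not
exercised by the test suite.

## What the phantom generator emulates — and what it does not

Real CCTA data cannot ship with the package, so `generate_phantom()`
builds the structures the pipeline depends on: a contrast-filled aortic
root as a vertical tube (default radius 15 mm, attenuation ~450–600 HU)
spanning the volume, an LM tube (radius 2.25 mm) leaving the aortic wall
horizontally at a configurable height, an RCA tube on the opposite side
at a different height, soft-tissue background (50 HU), and i.i.d.
per-voxel Gaussian noise of known SD. Geometry is analytic (voxel
centers inside each tube's signed distance), labels are the noise-free
geometry, and everything is bit-reproducible from a seed. The default
grid is 48 x 80 x 80 voxels at (0.9, 0.66, 0.66) mm — large enough for a
full seven-slice zone with realistic root caliber, small enough that a
phantom generates in tens of milliseconds.

`generate_cohort()` adds the three diagnostic-quality categories used in
image-quality research (fully diagnostic, diagnostic with excluded
parts, non-diagnostic). Group proportions default to 158 : 341 : 29 and
the label-conditional noise and attenuation distributions are Gaussians
whose medians (33.1 / 36.1 / 42.1 HUsd; 533.7 / 502.0 / 466.0 HU) and
spreads (IQR / 1.349) come from published group summaries of a large
single-scanner CCTA cohort. Phantoms in the intermediate group carry an
excluded-vessel fraction with a weak positive dependence on their
injected noise (`0.1 + 0.015 (SD − 30) + N(0, 0.15)`, clamped to [0, 1]),
emulating the weak published noise/excluded-length correlation. The
published sources report no distributional form, only medians and IQRs,
so the Gaussian choice and the link noise level are free parameters of
the emulation — they are stated here once and not tuned.

The phantom is deliberately *not* anatomy: no curved vessels, motion
blur, beam hardening, streaks, or spatially correlated noise (real CT
noise has a reconstruction-kernel-dependent texture; the i.i.d. model is
sufficient to exercise SD-based measurement, which is the quantity of
interest). Passing tests on phantoms therefore demonstrate that the
geometry, measurement and statistics machinery is correct — not that
the shipped toy network would segment clinical CCTA, which requires
training on real annotated studies at full scale.

## The statistical layer

`agreement_report()` compares automatic against manual measurements the
way method-comparison studies do: Spearman rank correlation (average
ranks; two-sided p from the t approximation), Bland–Altman bias with
1.96 SD limits of agreement plus a one-sample test of the bias, and mean
absolute difference / mean absolute relative error with normal 95% CIs,
the manual value serving as the reference denominator.

`group_compare()` reports median and IQR per quality group with pairwise
two-sided Mann–Whitney U tests. The groups are independent samples, so
the unpaired U test is used throughout (a paired test has no pairing to
exploit here); a Lilliefors-corrected Kolmogorov–Smirnov normality
screen is reported alongside, motivating the median/IQR presentation.

`roc_analysis()` quantifies how well noise (higher = worse) or SNR
(lower = worse) detects non-diagnostic studies: trapezoidal AUC, DeLong
95% CI, and a cutoff chosen by the Youden index, with sensitivity and
specificity at that cutoff. Youden is an explicit assumption — cutoff
selection criteria are rarely stated in the applied literature — and is
reported as such. ROC internals are delegated to pROC; the test suite
cross-checks the AUC against brute-force concordant-pair counting and
the other statistics against hand-computed or exhaustively enumerated
oracles. No multiplicity correction is applied.

`snr_from_thresholds()` records the arithmetic identity connecting
threshold conventions: an attenuation threshold of 400 HU with a noise
threshold of 30 HU corresponds to SNR 400/30 = 13.3.

## Problem sizes used by the tests and the acceptance script

The test suite trains the toy network on 8 phantoms with 2 held out
(32 x 48 x 48 voxels, aorta radius 8 mm), calibrates the estimators over
200 default phantoms with injected noise SD 35 HU, and checks cohort
discrimination over 20 independent 300-phantom cohorts. The acceptance
script additionally runs a 60-study automatic-vs-manual comparison and
one 529-study cohort evaluation. These sizes are the package's
desk-scale choices: large enough for stable medians, correlations and
DeLong intervals, small enough to run on one CPU in minutes.

## Known limitations

- The shipped network configuration is a toy; clinical use requires
  full-scale training on annotated CCTA studies.
- The phantom's noise is white; measurements on real reconstructions
  include noise correlation that the generator does not emulate.
- DICOM support covers uncompressed explicit-VR little-endian axial
  series only; anything else errors loudly rather than guessing.
- Only axis-aligned volumes are handled; oblique acquisitions must be
  reoriented upstream.
- Noise is measured at a single anatomical level; focal noise elsewhere
  in the heart is out of scope.
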