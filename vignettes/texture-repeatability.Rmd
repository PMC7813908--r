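---
title: "Quantifying MRI texture-feature repeatability and robustness on simulated phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying MRI texture-feature repeatability and robustness on simulated phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(texrep)
```

## Scope and model

`texrep` asks two questions about radiomic texture features extracted from
MR images: how much does a feature move when acquisition noise or spatial
resolution changes (*robustness*), and how well does it agree between two
acquisitions of the same object (*repeatability*)? Both are studied on
simulated phantoms so that every link of the imaging chain is controlled and
seeded.

The simulation deliberately stops short of MR physics: there is no Bloch
simulation, no k-space model, and no B0/B1 inhomogeneity. Contrast weighting
(T1/T2), TR/TE and the other sequence parameters are carried as protocol
metadata only. What *is* modelled is exactly the part of the chain the
metrics see:

* **Object.** A disc centred in the field of view. The water phantom is
  uniform; the tissue phantom adds a stationary Gaussian random field inside
  the disc — white noise smoothed with a Gaussian kernel whose width is the
  texture correlation length, rescaled to the requested SD. This is the
  simplest stationary texture with a tunable length scale; real muscle
  texture is anisotropic and non-Gaussian, so passing tests here demonstrate
  correctness of the measurement chain, not realism of the tissue model.
* **Noise.** Magnitude-MRI noise. At the SNR regime simulated (≈ 3.7–4.7 at
  NEX = 1) Rician noise is essentially Gaussian, so the Gaussian model is
  the default; the exact Rician magnitude model is available
  (`apply_acquisition_noise(model = "rician")`).
* **Repositioning.** One rigid in-plane transform per retest arm
  (translation uniform within ±2 mm per axis, rotation within ±1°, bicubic
  resampling, zero fill). Phantom repositioning with fiducial markers is
  accurate, so the defaults are small; they are configuration fields, not
  constants, because no measured repositioning error is available.

## Feature definitions and numerical choices

Each circular ROI yields 46 features. The 14 first-order statistics are
computed on the **raw** intensities — mean, median and RMS would be
identically 0/0/1 after normalization and are reported as informative
features. Entropy and uniformity use a 16-bin equal-width histogram over
[min, max]; 16 matches the grey-level count used downstream (the binning is
configurable). Kurtosis is non-excess (a normal distribution gives 3);
skewness, SD and variance use population (n) denominators.

Before the texture matrices, the ROI is z-normalized and quantized to
G = 16 uniform bins. The quantization range is **fixed** at ±3.29 in z units
(the two-sided 99.9 % normal quantile), with clipping: every ROI then shares
identical bin edges, which makes "uniformly spaced bins" reproducible across
ROIs and conditions. Per-ROI min–max binning is available as an option.
Bins are half-open with the last bin closed, so z = −3.29 maps to level 1,
z = 0 to level 9, and z = +3.29 to level 16. A constant ROI (e.g. a
noise-free water phantom) cannot be z-scored; the documented fallback maps
it to the middle grey level so that degenerate inputs remain processable,
and the affected GLCM features with zero marginal variance (correlation,
IMC1/2) return 0 with a warning.

The GLCM counts symmetric co-occurrences at distance 1 along the four
in-plane directions (0,1), (1,0), (1,1), (1,−1); pairs that leave the mask
are skipped; direction matrices are averaged and normalized to sum 1. The
GLRLM counts maximal equal-level runs along the same four directions (mask
gaps break runs); the direction matrices are padded to a common maximum run
length and averaged element-wise, and run totals (Nr) come from the averaged
matrix while the pixel total (Np) is the mask size. All logarithms are base
2 with 0·log 0 = 0. Sum variance is centred on the sum entropy — the
centring used in Haralick's original feature list, carried through the
standard radiomics compilations. `S.En` (intensity energy) and `T.En` (GLCM
angular second moment) are deliberately distinct features.

These computations are verified in the test suite against independent
brute-force enumerators (pixel-pair loops, run walkers, and double-loop
feature formulas) on hundreds of random small images, to 1e-10.

## Perturbation experiments

*Noise ladder.* The base image is treated as noise-free; Gaussian noise of
SD σ/√NEX is added in a single pass per level (never compounded), for
NEX ∈ {1, 7, 13, 19, 25, 31}, each level on an independent substream of the
ladder seed. σ is tied to the measured SNR at NEX = 1 through
σ = mean intensity / SNR with default SNR 3.75 (T2-like) and 4.69 (T1-like).
In the full study the base itself carries a residual noise realization at
the NEX = 32 level: base images are acquisitions, not ideal objects, and
this also keeps the uniform water phantom non-degenerate under the
resolution ladder. The consequence — simulated noise at NEX = 32 is not
equal to base-image noise — is inherent to the adding-noise design and
documented rather than removed.

*Resolution ladder.* The base volume is downsampled to round(256/r) pixels
per side, r = 1…6 (256, 128, 85, 64, 51, 43; nearest-integer rounding keeps
the field-of-view error below one pixel), with the Keys cubic-convolution
kernel (a = −0.5) and an antialiasing prefilter (kernel support widened by
1/scale) — the standard imresize behaviour. Pixel spacing is rescaled so the
field of view is constant, and the ROI centre/radius rescale with matrix
size so the physical region measured is constant.

*SNR estimation.* The two-image difference method: mean of the averaged
image over the ROI divided by SD(difference)/√2, pooling ROI pixels across
slices. The estimator recovers an injected σ within 5 % at ≥ 10⁴ ROI pixels
(tested over 20 seeds).

## Metrics and classification

Robustness per feature: the per-condition feature value is the mean over the
five slices, `%COV` is 100 · sample-SD / |mean| across the six conditions,
and the Pearson correlation is taken against NEX (noise) or matrix size
(resolution). The absolute mean handles sign-crossing features; a mean at
(near) zero makes the ratio meaningless and is flagged unclassifiable
rather than reported as an explosive value — mirroring the observed
instability of features like cluster shade. Classes: high %COV < 5,
mid 5–30, low > 30; correlation high |r| > 0.8, low |r| < 0.2 (the absolute
value, since strongly negative trends are equally "strong"). Boundary values
fall into the middle/lower class.

Repeatability per feature: Lin's CCC with population moments (his original
definition) over pairs pooled across phantoms, protocols of one weighting,
and slices — the pooling is a design choice (per-phantom CCC can be computed
by filtering the feature tables). Classes: poor < 0.90, moderate < 0.95,
substantial ≤ 0.99, near-perfect > 0.99.

## Problem sizes and what the defaults show

The default study uses 256×256 slices (five per arm), a 60-pixel-radius ROI
(≈ 11 300 pixels), both phantoms, six noise and six resolution levels, and
three protocols per weighting in the test-retest arms. The acceptance suite
averages the robustness study over 20 master seeds — these sizes run on one
CPU in a couple of minutes and give Monte-Carlo stability for the
qualitative claims tested: location features (S.Mean, S.Med, S.RMS) sit in
the high-robustness band for both ladders, and a test-retest with zero
jitter and shared noise seeds yields CCC = 1 for all 46 features.

```{r study, eval = FALSE}
cfg <- study_config(master_seed = 7)
study <- run_phantom_study(cfg, out_dir = "out")
summary(study)
```

## Known limitations

* The synthetic texture is stationary, isotropic and Gaussian; feature
  *memberships* in the robustness/repeatability classes depend on the
  object's true texture spectrum and will differ on scanner data.
* Resolution reduction is an image-domain resize, not k-space truncation;
  ringing and partial-volume behaviour of real low-matrix acquisitions are
  only approximated.
* Noise is added to an already-noisy base at high NEX; the ladder's
  effective noise is slightly above nominal at large NEX.
* The CCC assumes paired series from one population; pooling phantoms mixes
  two objects and is reported as such.
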