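# texrep

Repeatability and acquisition-parameter robustness of MRI radiomic texture
features, studied end-to-end on simulated phantoms.

## The problem

Radiomic texture features extracted from MR images are only useful for
clinical modelling if they are (a) *repeatable* — stable when the same object
is imaged twice — and (b) *robust* — insensitive to acquisition parameters
such as image noise (number of excitations, NEX) and matrix size
(resolution). `texrep` provides a fully seeded pipeline for quantifying both
on phantom images:

1. **Phantom simulation** — a uniform "water" disc and a textured "tissue"
   disc (stationary Gaussian random field of chosen SD and correlation
   length), magnitude-MRI noise (Gaussian or Rician), and rigid
   test–retest repositioning jitter with bicubic resampling.
2. **Feature extraction** — 46 radiomic features per circular ROI:
   14 first-order statistics on raw intensities, and 32 second-order
   features from the grey-level co-occurrence matrix (GLCM, Haralick) and
   grey-level run-length matrix (GLRLM, Galloway), computed after per-ROI
   z-normalization and quantization into G = 16 uniform grey-level bins
   over the fixed z-range ±3.29, with averaging over the four in-plane
   directions.
3. **Perturbation ladders** — noise injection with SD σ/√NEX for
   NEX ∈ {1, 7, 13, 19, 25, 31} (σ set from the difference-method SNR at
   NEX = 1), and resolution reduction to round(256/r) pixels, r = 1…6, by
   bicubic interpolation with antialiasing.
4. **Metrics** — per feature:
   - robustness: `%COV = 100 · SD/mean` across a ladder
     (high < 5 ≤ mid ≤ 30 < low), plus the Pearson correlation of the
     feature with NEX or matrix size (high |r| > 0.8, low |r| < 0.2);
   - repeatability: Lin's concordance correlation coefficient between the
     test and retest arms,

     CCC = 2ρσₓσᵧ / (σₓ² + σᵧ² + (μₓ − μᵧ)²),

     binned as poor (< 0.90), moderate (< 0.95), substantial (< 0.99) and
     near-perfect (> 0.99).

Real NIfTI volumes can be substituted for the synthetic phantoms at any
stage (`read_volume_nifti`, `run_condition_sweep`).

## Worked example

```r
library(texrep)

cfg <- study_config(master_seed = 7)
rb  <- run_robustness(cfg)    # noise + resolution ladders, both phantoms
rp  <- run_test_retest(cfg)   # test-retest CCC, T1- and T2-weighted arms
print(rb)
print(rp)
```

Output printed by the code above:

```
Texture-feature robustness (per phantom, per parameter)
  noise      high 52 | mid 25 | low 15 | unclassifiable 0
  resolution high 41 | mid 27 | low 24 | unclassifiable 0
  highly robust to both: S.Ent, S.Kur, S.Mean, S.Med, S.RMS, T.Aut, ...
  184 rows; first rows:
  phantom feature parameter     pct_cov robustness_class  pearson_r correlation_class
1   water    S.En     noise  2.68100065             high -0.7304360               mid
2   water   S.Ent     noise  0.95784825             high -0.3309702               mid
...
Texture-feature test-retest repeatability (CCC)
  T1: poor 9 | moderate 4 | substantial 7 | near-perfect 26
  T2: poor 11 | moderate 1 | substantial 12 | near-perfect 22
```

Reading: each of the 46 features gets a `%COV` across the six noise levels
and across the six resolutions (per phantom), its robustness class, and its
linear correlation with the acquisition parameter; location features such as
`S.Mean`, `S.Med` and `S.RMS` stay in the high-robustness band because the
normalisation-free location of the signal is barely moved by zero-mean noise
or by interpolation. In the test–retest experiment roughly 80 % of features
reach CCC ≥ 0.9 under small repositioning jitter (2 mm, 1°) with fresh noise
realizations — texture features driven by high-order co-occurrence moments
(e.g. cluster shade) degrade the most.

`run_phantom_study(cfg, out_dir = "out")` writes `robustness_noise.csv`,
`robustness_resolution.csv`, `repeatability_T1.csv`, `repeatability_T2.csv`
and `summary.json`.

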