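---
title: "Methods: SVM texture classification of diffuse marrow infiltration"
author: "marrowtex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SVM texture classification of diffuse marrow infiltration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

On T1-weighted MRI, normal adult vertebral marrow is fat-rich and bright;
diffuse hematologic infiltration (myeloma, leukemia, lymphoma, and related
conditions) replaces fat with cells and lowers the signal *uniformly across
all vertebrae*, so there is no focal lesion for a reader to anchor on. The
pipeline treats the problem as binary texture classification: raw pixel
intensities from rectangular windows over the S1–L1 vertebral bodies, after
normalization to an internal disk reference, are the feature vector of a
soft-margin C-SVM. No derived texture descriptors are computed — the kernel
machine performs its own implicit feature weighting, and filtering
front-ends (autoregressive models, wavelets) are deliberately out of scope.

The stages and their assumptions:

1. **Disk normalization.** Each volume is shifted by the mean intensity of
   the annulus fibrosus of the subject's most cranial non-degenerated
   intervertebral disk. The disk is split into five equal-width bins along
   its anterior–posterior extent; bins 1 and 5 are the annulus. Subtracting
   a scalar reference makes the features invariant to global intensity
   offsets, which is the dominant component of between-scanner
   heterogeneity. A scalar (not pixelwise) subtraction is used because
   pixelwise subtraction is ill-defined between regions of different size;
   shift invariance — the purpose of the normalization — is exactly what the
   scalar version provides, and it makes the operation idempotent.
2. **GrowCut segmentation.** A seeded cellular automaton on the voxel graph
   (26-connectivity in 3D, 6-connectivity available): each voxel carries a
   label and a strength θ ∈ [0, 1]; seeds start at θ = 1; neighbor q
   conquers p when g(|I_p − I_q|)·θ_q > θ_p with the attack attenuation
   g(x) = 1 − x/maxdiff clamped to [ε, 1 − ε], ε = 10⁻⁶ and maxdiff the
   volume's intensity range. The clamp's upper bound keeps strengths
   strictly decreasing along every conquest chain (termination), and the
   strict inequality means seeds are never conquered. Updates are
   synchronous (Jacobi-style) so the result is independent of voxel visit
   order — reproducibility is preferred over the faster in-place variant.
   Seeds are produced automatically by eroding the ground-truth marrow
   labels (foreground) and the non-marrow remainder (background); disks and
   soft tissue are part of the background class because the segmentation
   target is marrow alone.
3. **Featurization.** The window is population-minimal: the smallest
   per-level, in-slice marrow bounding box across the cohort sets the
   height and width, so every subject contributes the same dimension
   6 × height × width × n_slices with n_slices ∈ {1, 3, 9} consecutive
   sagittal slices centred on the mid-sagittal slice. Windows are anchored
   at each level's in-slice marrow centroid (deterministic and mask-driven;
   the anchoring rule is otherwise unconstrained by the design). All pixels
   inside the window are used, masked or not, because a mask-restricted
   read could not guarantee a fixed dimension. Features are min–max scaled
   to [0, 1] with parameters fitted on the training matrix only and reused
   unchanged on the test matrix (train-fitted scaling avoids information
   leakage; constant training columns map to 0, out-of-range test values
   are preserved).
4. **Classification.** Soft-margin C-SVM (libsvm through e1071) with three
   kernels: 3rd-order polynomial (γ·u'v + coef0)³, tangent hyperbolic
   tanh(γ·u'v + coef0) and RBF exp(−γ‖u−v‖²); coef0 defaults to 0. (C, γ)
   are chosen by exhaustive grid search scored by stratified 5-fold
   cross-validation accuracy; the default grids are the canonical libsvm
   practical-guide ranges C ∈ 2^{−5,−3,…,15}, γ ∈ 2^{−15,−13,…,3}. Ties
   break toward the smallest C then the smallest γ (a preference for the
   smoother model). Stratification prevents empty-class folds at small n.
   γ is optimized for all three kernels uniformly. The decision threshold
   is fixed at score 0 but exposed as a parameter.
5. **Evaluation.** Accuracy, sensitivity and specificity carry Wilson score
   95% intervals — chosen because the Wilson interval exactly reproduces
   all six printed worked-example bounds from the published test
   composition (n = 107; 45 control, 62 diseased), so it is treated as the
   inferred specification. AUC is the Mann–Whitney pairwise probability
   (ties one half), identical to the trapezoidal area under the empirical
   ROC; its variance and the paired two-AUC comparison use DeLong's
   structural components, hand-implemented so that pROC can serve as an
   independent cross-check in the tests. McNemar's test uses the exact
   two-sided binomial below 25 discordant pairs and the
   continuity-corrected chi-square above (conventional switch). Cohen's κ
   uses the standard marginal-product expectation with interpretation
   bands at 0.2 steps; the degenerate both-raters-constant case is defined
   as κ = 1 and flagged. Reader confidence is ordinal 0–4 and binarized at
   3 (0–2 negative).
6. **Learning curve.** Performance versus training size is fitted by the
   inverse power law y(x) = (1 − a) − b·x^c — a the minimum achievable
   error, b the learning rate, c the decay rate — with weighted
   Levenberg–Marquardt least squares (minpack.lm), unit weights by
   default, initialization a₀ = 1 − max(y), b₀ = 1, c₀ = −0.5, tolerances
   10⁻¹⁰. SSE = Σ wᵢ(yᵢ − ŷᵢ)² and RMSE = √(SSE/(n − m)), m = 3. The
   model is undefined at x = 0 for c < 0, so chance-level points at size 0
   are recorded but excluded from the fit with a message — preferable to
   inventing an offset term the model family does not contain. The curve
   is inverted analytically for the size required to reach a target
   (error if the target exceeds the asymptote 1 − a); 95% prediction
   bounds come from the delta method, ŷ ± t_{n−m}·√(gᵀΣg + s²).

## The synthetic phantom: what it emulates and what it does not

No patient images are distributed with the study this package
re-implements, so all experiments run on a stylized, fully seeded phantom.
It emulates exactly the properties the classifier exploits:

- **Geometry**: a 2D-extruded sagittal spine — rectangular vertebral bodies
  (level 1 = S1, most caudal; rows increase superior→inferior), lens-shaped
  disks between adjacent bodies, a posterior soft-tissue band, nine slices
  by default so the 9-slice feature setting is exercisable. Anatomical
  labels are exact ground truth. No stage depends on realistic anatomy
  beyond per-level connected regions and disk compartments.
- **Marrow texture**: a stationary correlated Gaussian random field (white
  noise smoothed by an isotropic Gaussian kernel of scale
  `textureCorrLen`, then re-centred and re-scaled exactly over the marrow
  voxels). Controls: mean 150, SD 8. Diseased: mean 110, SD 16 — diffusely
  lowered mean and raised heterogeneity relative to the disk nucleus
  (120) and annulus (60). The published study gives no quantitative
  description of diseased texture, so these effect sizes are fixed design
  choices of the generator (the default contrast is five normal texture
  SDs), not claims about real data.
- **Scanner heterogeneity**: a per-subject global affine intensity map
  (offset uniform in ±20, scale in [0.9, 1.1]) plus i.i.d. Gaussian noise
  (SD 5). An affine perturbation is exactly the distortion that disk
  normalization should (partially) remove: the offset cancels, the scale
  survives as residual heterogeneity.
- **Confounds**: optional focal insertions — fracture-like (row collapse +
  intensity drop), hemangioma-like (bright blob), Modic-like (endplate
  band) — so confound analyses can be replayed.

Per-subject RNG streams are child seeds drawn through the master-seeded
generator (`sample.int`) rather than by an arithmetic formula: seeding
Mersenne–Twister along a congruential progression can leave residual
correlation between streams, which a null cohort turns into spurious class
signal.

It does **not** emulate MR physics (relaxometry, bias fields, k-space
artifacts), demographic covariates of marrow cellularity, red-marrow
reconversion, or realistic vertebral shape. Consequently, a passing
end-to-end suite demonstrates that the pipeline is correct and behaves
lawfully (separates separable cohorts, stays at chance on
distribution-identical ones, improves with training size) — it does not
certify clinical-grade accuracy on real images.

## Numerical and design choices

- GrowCut conflict resolution: among simultaneous successful attackers the
  strongest wins; exact ties go to the first offset in lexicographic
  (dz, dy, dx) order. The brute-force oracle in the test suite implements
  the same rule per voxel, independently.
- Erosion for automatic seeding uses a Chebyshev ball; out-of-volume
  neighbors count as inside, so border regions keep seeds.
- `requiredSampleSize` returns ⌈x*⌉ for non-integral solutions and x* + 1
  when x* is integral within 10⁻⁸ — the returned size always strictly
  exceeds any not-yet-attained real-valued solution while round-tripping
  `evaluateCurve` at non-integral sizes.
- Reference-disk tie-break: most cranial non-degenerated disk.
- The fixed held-out test set is reused across all sweep conditions, and
  training subsets are drawn class-balanced at every size, matching the
  balanced 180:180 training design.
- Kappa bands are compared with a 10⁻⁹ tolerance so a computed 0.6 falls
  in the moderate band as printed, not in substantial via float noise.

## Problem sizes used by the tests and the acceptance script

The test suite and `scripts/acceptance.R` run the full pipeline on phantoms
of shape 3 × 60 × 48 with single-slice features and reduced grid-search
ranges (C ∈ 2^{−1,3,7}, γ ∈ 2^{−9,−5,−1}), at the full cohort composition
(180:180 training, 45:62 test); the training-size sweep uses sizes
60/120/240 with 3 repetitions; learning-curve recovery uses the twelve
positive sizes 10–360 with 500 noisy replicates; GrowCut oracle equality is
checked on 4×4×2 (to convergence) and 16³ (fixed sweep count) volumes, and
segmentation Dice on a full-size default phantom (9 × 256 × 192). These
sizes were chosen so the whole verification runs in minutes on a laptop
while still exercising every code path at the study's cohort composition.

## Known limitations

- The phantom's texture model is stationary and Gaussian; real marrow
  texture is neither, and the study's raw-pixel features may behave
  differently under non-stationarity.
- Window anchoring (centroid) and slice-stack placement (centred) are
  fixed conventions; the original acquisition protocol does not constrain
  them, and other conventions would yield different realized dimensions.
- The learning-curve asymptote a is weakly identified from few, noisy
  points: its single-fit spread at noise SD 0.01 is ≈ 0.04, so required
  sample sizes inverted near the asymptote carry wide uncertainty (the
  prediction bounds quantify this).
- DeLong variance is asymptotic; at very small n the AUC CI can degenerate.
- GrowCut here is the reproducible synchronous variant; in-place
  (Gauss–Seidel) implementations converge faster but depend on visit
  order.
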