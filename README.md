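# marrowtex

Diffuse hematologic marrow infiltration replaces bright fatty marrow with
cellular infiltrate on T1-weighted lumbar-spine MRI, lowering the signal
diffusely — precisely the pattern that is hardest to call by eye because no
focal contrast exists. `marrowtex` implements, as a tested and reusable R
pipeline, an SVM texture-classification study of this problem: raw marrow
pixels from sagittal T1 images are fed to a support vector machine that
separates diffusely infiltrated from normal marrow, and a learning-curve
model estimates how many training cases a target accuracy requires.

Because the original patient images are not publicly available, the package
ships a seeded synthetic spine-phantom generator that reproduces the
statistical structure the classifier exploits (marrow texture contrast, disk
compartments, per-scanner intensity heterogeneity, focal confounds), so
every stage is testable end to end on any machine.

The pipeline stages, each an exported function group:

1. **Phantom** — `phantomConfig()`, `generateCohort()`,
   `injectFocalLesion()`: cohorts of `SpineSubject` volumes with exact
   ground-truth labels (NIfTI + JSON round-trip via `saveSubject()`).
2. **Preprocess** — `normalizeByDisk()` subtracts the mean annulus-fibrosus
   intensity of the most cranial non-degenerated disk (the annulus is the
   outer two of five equal anterior–posterior disk bins), removing
   per-scanner offsets; `growCutSegment()` segments marrow with a 3D GrowCut
   cellular automaton: neighbor `q` conquers voxel `p` when
   `g(|I_p − I_q|)·θ_q > θ_p`, `g(x) = 1 − x/maxdiff`, synchronous updates.
3. **Featurize** — `computeMinWindow()` finds the population-minimal
   rectangular window covering the smallest vertebral marrow;
   `extractFeatureVector()` reads six windows (S1–L1) per slice over 1, 3 or
   9 consecutive slices; `minmaxScale()` maps features to [0, 1] with
   train-fitted parameters.
4. **Classify** — `gridSearchCV()` (stratified 5-fold CV over the canonical
   `C = 2^-5..2^15`, `γ = 2^-15..2^3` grids), `trainSvm()` /
   `predictSvm()` with 3rd-order polynomial, tangent-hyperbolic and RBF
   kernels (libsvm via e1071).
5. **Evaluate** — `confusionMetrics()` (Wilson 95% CIs), `rocAuc()` and
   `compareAuc()` (DeLong), `mcnemarTest()`, `cohenKappa()`,
   `binarizeScores()` for five-level reader confidence.
6. **Learning curve** — `fitInversePower()` fits
   `y = (1 − a) − b·x^c` (minimum achievable error `a`, learning rate `b`,
   decay rate `c`) by Levenberg–Marquardt; `requiredSampleSize()` inverts it.
7. **Orchestrate** — `runFullExperiment()` chains everything and writes
   `fig1_data.csv`, `table1.csv`, `table2.csv`, `fig3_points.csv`.

## Worked example

```r
library(marrowtex)

cfg  <- phantomConfig(imageShape = c(3L, 60L, 48L))
subj <- generateSubject(cfg, diseaseStatus = 1L, seed = 3L)
pp   <- preprocessSubject(subj, erosionRadius = 1L)
pp$mask
#> MarrowMask: 1911 foreground voxels; 7 iterations; converged
truth <- anatomyLabels(subj) >= 1 & anatomyLabels(subj) <= 100
diceCoefficient(maskArray(pp$mask), truth)
#> [1] 0.9753567

spec <- computeMinWindow(list(pp$subject), list(pp$mask), nSlices = 1L)
spec
#> WindowSpec: 6 x 18 window, 6 levels x 1 slice(s); dimension 648

m <- confusionMetrics(pred = c(rep(1, 88), rep(0, 19)), truth = rep(1, 107))
formatMetricsRow(m)$CA
#> [1] "82.2 [73.9-88.3]"

f <- fitInversePower(c(10, 20, 40, 80, 160, 320),
                     evaluateCurve(c(a = .15, b = 1.2, c = -.4),
                                   c(10, 20, 40, 80, 160, 320)))
f
#> LearningCurveFit: y = (1 - 0.15) - 1.2 * x^(-0.4)
#>   SSE = 5.547e-32, RMSE = 1.36e-16 on 6 points
requiredSampleSize(c(a = 0.15, b = 0.9, c = -0.5), target = 0.84)
#> [1] 8101
```

The segmentation Dice of 0.975 means GrowCut recovered nearly all
ground-truth marrow on a diseased (high-heterogeneity) phantom; the
bracketed percentages are Wilson
95% confidence bounds for 88 correct calls out of 107; the learning-curve
fit recovers its generating coefficients to machine precision, and the
inversion says 8101 training subjects are needed for 84% accuracy under
those coefficients.

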