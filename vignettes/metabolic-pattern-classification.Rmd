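---
title: "Voxel-wise SVM classification of FDG-PET volumes: methods and design"
author: "petstratify"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-wise SVM classification of FDG-PET volumes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Roughly nine in ten Parkinson's disease patients with mild cognitive
impairment (PD-MCI) eventually progress to dementia (PDD), but the timing
varies by many years and baseline neuropsychology predicts it poorly.
Regional glucose metabolism measured by FDG-PET changes ahead of the
clinical decline, so a multivariate classifier trained on baseline scans of
patients whose outcome is already known can be used as a prognostic
biomarker: a new patient's scan is reduced to a single *subject score*, and
the sign of that score is the predicted outcome.

`petstratify` implements this pipeline end to end — preprocessing, a
voxel-wise soft-margin linear SVM, cross-validation, permutation inference
on the weight map, spatial pattern comparison, and frozen-model application
to external cohorts — together with a synthetic cohort generator that makes
every stage testable without patient data.

# The model

Each subject is a volume $x \in \mathbb{R}^V$ over the $V$ brain-mask
voxels, preprocessed as described below.  Training data
$(x_i, y_i)$, $y_i \in \{-1, +1\}$ ($+1$ = converter), enter the
soft-margin problem

$$
\min_{w, b, \xi} \; \tfrac{1}{2}\lVert w \rVert^2
  + \sum_i C_i \xi_i
\quad \text{s.t.} \quad
y_i (w \cdot x_i + b) \ge 1 - \xi_i, \; \xi_i \ge 0,
$$

solved in the dual with the kernel
$k(x, x') = x \cdot x' / s^2 + c_0$ (scale $s$, offset $c_0$).  Because the
dual solution satisfies $\sum_i \alpha_i y_i = 0$, the offset term
contributes exactly zero to the decision function; it is absorbed, and the
exported model is always the equivalent primal pair $(w, b)$.  The subject
score is $w \cdot x + b$ and the predicted label is $1$ iff the score is
strictly positive (a score of exactly 0 is classified stable — "positive
means converter" makes non-positive the conservative default).

## Parameters

| parameter | default | meaning |
|---|---|---|
| `outlierFraction` | 0.05 | fraction of largest-slack training points excluded by a single trimming refit |
| `cost` | `[[0,1],[1,0]]` | per-class misclassification costs; class $a$'s box is `boxConstraint * cost[a, other]` |
| `kernelOffset` | 0.1 | constant added to every inner product (no effect on the exported decision function; see above) |
| `kernelScale` | 1 | inner-product divisor $s$ |
| `boxConstraint` | 1 | base box constraint $C$ |
| `tolerance` | 1e-8 | maximal KKT violation at convergence |
| `maxIterations` | 1e6 | iteration cap; exceeding it raises a warning and flags the model |

The dual is solved by a deterministic maximal-violating-pair SMO
(two-variable analytic updates, lowest-index tie-break), so identical
inputs always produce bit-identical weights; the `seed` in the parameters
is provenance only.  The contract is the optimization problem, not any
particular solver: the test suite checks the solution against an
independent implementation (libsvm via `e1071`) to $10^{-4}$ relative on
subject scores, and against the KKT conditions directly.

`outlierFraction` deserves a note: robust SVM variants differ in how they
down-weight gross outliers, and the mechanism used here is documented
trimming — fit, drop the `floor(f * n)` training points with the largest
slack, refit once.  With `outlierFraction = 0` the plain SVM is recovered
exactly.

# Preprocessing

Volumes are assumed spatially co-registered (warping to a standard space is
out of scope).  Each volume is

1. **smoothed** with an axis-separable Gaussian,
   $\sigma_\text{axis} = \mathrm{FWHM} / (2\sqrt{2\ln 2}) /
   \text{voxelsize}_\text{axis}$, default FWHM 8 mm.  The kernel is
   truncated at $4\sigma$ and renormalized within the grid, so constants
   are preserved exactly everywhere including the boundary; away from the
   boundary the operation matches a brute-force dense convolution oracle to
   $10^{-6}$;
2. **proportionally scaled** so that its mean over the brain mask equals a
   target (default 50, the conventional grand mean).  The "whole-brain
   mean" is taken over an explicit mask, never over the rectangular grid —
   background voxels would dilute it arbitrarily.  The target itself only
   scales all scores by a common factor; it is recorded and enforced, not
   meaningful;
3. **masked and flattened** over the mask voxels in ascending linear
   (column-major) index order.

The order is smooth *then* scale; the two orders genuinely differ (smoothing
moves mass across the mask boundary and so changes the in-mask mean), and a
test constructs such a case and pins the implemented order.  The FWHM,
target, and a mask fingerprint form the *normalization record* stored in
both the feature container and every trained model; a frozen model refuses
features carrying a different record rather than silently rescaling.

# Cross-validation and performance

`kfoldScores()` performs stratified k-fold cross-validation (default
k = 10).  Stratification is the default because with ~40 subjects and
k = 10 unstratified folds can easily be single-class; it can be switched
off.  If the smaller class has fewer than k members, k is reduced with a
warning.  Metrics come from a single pooled out-of-fold confusion table
(one sensitivity/specificity/accuracy triple, matching how a k-fold model
is conventionally reported), plus the Mann–Whitney AUC of the pooled
scores with ties counted one half.  Rates with empty denominators are
returned as `NA` ("undefined"), never as `NaN`.

Proportions from two classifiers (e.g. cross-validated vs external test
set) are compared with Pearson's $\chi^2$ on the 2×2 success/failure
table, *without* Yates continuity correction — the uncorrected statistic is
what standard reports of such comparisons print, and the package reproduces
the three reference values 1.380, 1.748 and 0.120 from their printed
counts.  p-values accompany the statistics but are never the acceptance
surface.

# Permutation inference on the weight map

The significance of each voxel's weight is assessed by retraining the full
model (identical parameters, including the trimming step) on label-shuffled
data — class sizes preserved — and counting, per voxel, how often the null
models' absolute weight reaches the true model's:

$$ p_v = \frac{\#\{\,r : |w^{(r)}_v| \ge |w_v|\,\}}{n_\text{eff}}. $$

Design choices:

* **Scale-free comparison.**  By default the comparison is made on
  unit-normalized weight maps $w / \lVert w \rVert_2$.  The global norm of
  a soft-margin solution reflects the achieved margin, not the topography:
  on a cleanly separable training set the true model's $\lVert w \rVert$
  is an order of magnitude *smaller* than that of its inseparable
  label-permuted counterparts (whose dual variables saturate at the box),
  and the raw-magnitude comparison then returns $p \approx 1$ everywhere
  regardless of how real the pattern is.  Normalization tests the quantity
  of interest — where the discriminating weight concentrates — and is
  calibration-preserving under the null by exchangeability.  When true and
  null models have comparable scales (the weakly separable regime typical
  of real cohorts) the two comparisons coincide; `normalizeWeights = FALSE`
  gives the raw variant.
* **Ties count as exceedances** (\(\ge\)), so the smallest attainable
  p-value in the presence of a tie is $1/n$ — the conservative, standard
  choice; a strict-inequality variant is behind `ties = "gt"`.
* **Plain proportion** by default; the add-one $(b+1)/(n+1)$ estimator is
  available behind `smoothing = TRUE`.
* **Uncorrected voxel-wise inference only.**  No FWE/FDR correction is
  applied, deliberately: the thresholded map is a descriptive pattern, and
  users should treat isolated suprathreshold voxels accordingly.
* A permutation whose fit fails is recorded and excluded; the count is
  reported.

The thresholded signed pattern (`thresholdPattern()`) equals the true
weight where $p < \alpha$ (default 0.05) and 0 elsewhere: positive values
mark relative hypermetabolism predictive of conversion, negative values
relative hypometabolism.  200–500 permutations are adequate for the
calibration and recovery checks in this package; production weight-map
inference conventionally uses 10,000.

# Spatial pattern similarity

`spatialCorrelation()` is the Pearson correlation of two maps over the
mask.  Its p-value cannot come from treating voxels as independent —
smooth maps have few spatial degrees of freedom — so
`autocorrSimilarityTest()` builds surrogate maps that preserve the first
map's 3-D Fourier *amplitude* spectrum while randomizing phases (phases are
taken from the FFT of a white-noise field, which guarantees a real-valued
surrogate), re-applies the mask, and re-matches the in-mask mean and
variance.  The p-value is two-sided on $|r|$ with the $(b+1)/(n+1)$
correction, so it lies in $(0, 1]$ and self-similarity attains exactly
$1/(n+1)$.  Variogram-matched or surface-spin surrogates are out of scope;
phase randomization is the documented stand-in with the same intent
(null maps of equal smoothness).

# The synthetic cohort generator

`simulateCohort()` provides the study conditions for every test:

* a deterministic ellipsoidal phantom (default grid 32×40×32 at 4 mm,
  ~16,800 mask voxels — coarse enough that full permutation suites run at
  desk scale, configurable upward), shell intensity ~1.0 rising to 2.5 in
  deep structures, with a mild anterior–posterior gradient;
* a planted signed effect field: ±amplitude inside spherical regions, the
  default layout being lobar-scale bilateral posterior/temporal
  hypometabolism plus medial-anterior and deep hypermetabolism (~3,200
  voxels, ~19% of the mask — lobar patterns are large);
* subject volumes $g_i \cdot (T \odot (1 + c_i E)) + \varepsilon_i$ with
  $c_i \in \{0, 1\}$ the class label, $g_i$ lognormal (median 1, log-SD
  0.1) modeling the global uptake/dose nuisance that proportional scaling
  exists to remove, and $\varepsilon_i$ i.i.d. Gaussian noise (SD 0.1 in
  template units) inside the mask.  Effects are multiplicative fractions
  of the template so hypo/hyper regions scale with local intensity.
  Default cohort size 20 + 23, a realistic single-center conversion
  cohort.

Defaults were chosen once as plausible study conditions: noise SD 0.1
against a shell intensity of 1.0 approximates the within-tissue coefficient
of variation of smoothed, count-limited clinical FDG-PET; amplitude 0.15
(default) and 0.30 (recovery checks) span subtle-to-strong regional
metabolic differences (10–30% regional changes are the range reported in
dementia imaging); the log-SD 0.1 global factor corresponds to ~10%
inter-subject dose variability.

What the generator does *not* emulate: scanner physics (scatter,
attenuation, partial volume), anatomical atlas fidelity, spatially
correlated physiological noise, registration error.  Passing tests
demonstrate the pipeline's statistical machinery — nuisance removal,
calibration, recovery, invariances — not clinical performance on real
scans.

# Numerical and testing choices

* **Problem sizes.**  Module unit tests run on a 12×14×12 phantom
  (~1,000 mask voxels); end-to-end checks run at the full default grid with
  200 permutations (null calibration, 20+20 subjects) and 500 permutations
  (pattern recovery, 25+25, amplitude 0.3).  The effect-size monotonicity
  check averages 10-fold CV accuracy over 10 seeds at amplitudes
  {0, 0.05, 0.15, 0.30}.
* **Null calibration band.**  With 200 permutations and ties counted, the
  nominal per-voxel $P(p < 0.05)$ is $10/201 \approx 0.0498$.  The
  suprathreshold *fraction* over ~1.7×10⁴ voxels is not binomial: 8 mm
  smoothing on a 4 mm grid leaves roughly $10^3$ spatially independent
  resolution elements, and all voxels share the same 200 label draws,
  which together inflate the variance well beyond
  $\sqrt{0.05 \cdot 0.95 / V}$.  The acceptance band [0.02, 0.08]
  (nominal ± 0.03) was fixed a priori from these two considerations.
* **Null CV accuracy.**  Cross-validated accuracy under no effect is
  checked against a ±0.15 band around 0.5 for a 10-seed mean: out-of-fold
  accuracy on null high-dimensional data is known to be slightly
  pessimistic (anti-learning), and seeds share the phantom.
* **Degenerate inputs** are errors, not warnings: empty masks, nonpositive
  whole-brain means, single-class training sets, non-finite voxels (the
  error names the affected voxel count), normalization-record mismatches,
  zero-variance paired differences (flagged undefined).
* **Model serialization**: weight maps are stored as float64 NIfTI so that
  a save/load round-trip preserves subject scores to $10^{-10}$ relative;
  images are float32 (the neuroimaging convention, and bit-exact for
  float32 payloads), masks uint8.  Model metadata lives in a readable JSON
  sidecar — a frozen clinical classifier should be auditable — which also
  records that scores include the bias term (so that `sign(score)` equals
  the classifier output).

# Known limitations

* Inference is per-voxel and uncorrected; the pattern map is descriptive.
* The phase-randomization surrogate preserves second-order spatial
  structure only; strongly non-Gaussian or nonstationary maps may need
  stronger surrogates.
* The outlier-trimming mechanism is a documented approximation to robust
  solver behavior, not a re-implementation of any particular solver's
  internals.
* The generator's planted effects are hard spheres; real metabolic
  patterns have graded boundaries, so recovered patterns on real data will
  be smoother than the test fixtures suggest.
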