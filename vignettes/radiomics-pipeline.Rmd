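---
title: "A radiomic texture benchmark for mutation-status prediction in brain-metastasis MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A radiomic texture benchmark for mutation-status prediction in brain-metastasis MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Activating EGFR mutations decide first-line therapy in advanced lung
cancer, and brain metastases (BMs) are often detected on a routine
contrast-enhanced T1-weighted MRI before any tissue from the metastasis is
available. The question this package operationalizes is whether the
*texture* of an enhancing metastasis carries enough information to predict
the patient's binary mutation status. The computational recipe is classic
radiomics: quantify each segmented lesion with a large fixed feature
vector, then benchmark a grid of feature-selection algorithms against a
panel of classifiers under cross-validation, and finally ask — via label
permutation — whether the best cell's performance could have arisen by
chance.

Because no patient imaging is distributed with this package, the pipeline
ships with a *synthetic cohort generator* whose role is to provide data
with the same structure (patients carrying multiple lesions, a per-patient
binary label, lesion sizes spanning an order of magnitude) and a
*controllable* class-texture difference, so that every stage can be tested
against a known ground truth: a planted effect must be recovered, an
absent effect must yield chance-level AUC and non-significant permutation
p-values.

## The feature vector

Each lesion is an intensity array plus a binary mask at known voxel
spacing. After preprocessing (below), exactly 1209 features are computed,
in a fixed registry order:

* **6 first-order** statistics of the in-mask intensity histogram: mean,
  population variance, moment skewness, excess kurtosis (both defined as 0
  for constant regions), histogram energy $\sum_b p_b^2$ and entropy
  $-\sum_b p_b \log_2 p_b$ over a 64-bin equal-width in-mask histogram.
* **25 second-order** texture statistics from two gray-level matrices
  computed on the ROI quantized to 32 equal-width levels between the
  in-mask minimum and maximum:
  * 14 Haralick statistics of the gray-level co-occurrence matrix (GLCM):
    angular second moment, contrast, correlation, sum-of-squares variance,
    inverse difference moment, sum average/variance/entropy, entropy,
    difference variance/entropy, the two information measures of
    correlation, and the maximal correlation coefficient. The GLCM is 3D:
    voxel pairs at distance 1 along all 13 unique directions, accumulated
    into one symmetric matrix (rotation-robust), pairs crossing the mask
    boundary skipped, $0\log 0 = 0$, correlation defined as 0 when a
    marginal SD vanishes.
  * 11 run-length statistics of the gray-level run-length matrix (GLRLM)
    over the same 13 directions: SRE, LRE, GLN, RLN, RP, LGRE, HGRE,
    SRLGE, SRHGE, LRLGE, LRHGE, with gray levels indexed from 1 for the
    low/high weighting and RP normalized by in-mask voxels times
    directions.
* **38 × 31 higher-order** features: the root filter set (RFS) bank — 36
  oriented anisotropic derivative-of-Gaussian kernels (first derivative
  "edge" and second derivative "bar" across the short axis; scales
  $(\sigma_s,\sigma_\ell) \in \{(1,3),(2,6),(4,12)\}$ voxels; 6
  orientations at $30^\circ$ steps) plus an isotropic Gaussian and a
  Laplacian-of-Gaussian ($\sigma = 10$) — applied slice-wise along the
  axial axis with reflect padding (FFT cross-correlation), then the same
  6 + 25 features computed within the mask on each response map.

$6 + 25 + 38 \times 31 = 1209$. Derivative kernels are forced exactly
zero-sum and L1-normalized; the Gaussian sums to one, so a constant volume
passes through the Gaussian unchanged and annihilates every derivative
kernel — both properties are tested.

Choices the published description leaves open, fixed here once: 32
quantization levels (configurable); response maps are standardized within
the mask before re-quantization — since equal-width quantization on the
in-mask range is affine-invariant this is a no-op for the texture features
but keeps first-order moments on the raw response scale; first-order
features of response maps are computed on the raw responses. Kernel
support is $49\times49$ at the largest scale and $2\lceil2.5\sigma_\ell\rceil+1$
at smaller ones; for lesions smaller than the support the reflect padding
tiles, which is well-defined and deterministic.

## Preprocessing

The stage order is fixed: multiplicative bias correction, crop,
normalize.

* **Bias correction** estimates the shading field as a heavy Gaussian
  low-pass (default FWHM 60 mm) of the positivity-shifted volume and
  divides it out, rescaling to preserve the masked mean. This is a
  low-pass surrogate targeting smooth multiplicative nonuniformity; it is
  *not* a histogram-sharpening nonuniformity solver, and it can be
  disabled with `bias = FALSE`.
* **Crop** takes the mask bounding box dilated by a 2-voxel margin.
* **Normalization** maps the cropped volume to zero mean, unit SD.
  Statistics are computed over the whole cropped volume (not mask-only),
  matching whole-image normalization; `region = "mask"` is available.
  Normalizing after cropping is a choice — the alternative order is
  supported by normalizing manually before `crop_to_roi()`.

## The synthetic cohort

`cohort_config()` defaults encode the emulated study conditions:

| parameter | default | meaning |
|---|---|---|
| `n_patients` | 61 | patients |
| `lesions_per_patient` | 1–12, mean 3.44 | truncated geometric-like counts |
| `diameter_mm` | 3–40, mean 10.6, sd 8 | truncated log-normal, longest axis |
| `class_fraction` | 29/61 | patients labeled mutant |
| `correlation_length_mm` | 1.5 (wild type) vs 3.0 (mutant) | Gaussian kernel SD of the interior random field |
| `field_sd` | 15 | texture SD on a base intensity of 140 |
| `rim_contrast` | 20 | bright shell emulating ring enhancement |
| `background_sd` | 5 | additive tissue noise around mean 100 |
| `bias_field_amplitude` | 0.2 | log-scale amplitude of the multiplicative bias |
| `voxel_spacing_mm` | (1,1,1) | isotropic 1 mm |

The interior texture is white Gaussian noise convolved with a separable
Gaussian of SD `correlation_length_mm`, rescaled voxel-wise by the exact
per-voxel SD of the smoother, so the marginal SD is exact everywhere
including boundaries. Only the second-order structure of the field matters
to the texture features, which is why a Gaussian-correlated field is the
right minimal model. The planted class effect is a doubled correlation
length — a pure texture-scale effect with no first-order intensity
difference in expectation, so recovering it requires the texture features
to work. Lesions are axis-aligned ellipsoids (longest axis = recorded
diameter, the two other semi-axes uniform in 70–100% of it, axes randomly
assigned); diameter is the 3D longest axis, the natural caliper analogue.
Labels are assigned per patient and shared by all of that patient's
lesions.

What the generator does *not* emulate: MRI acquisition physics, partial
volume at 1 mm, necrotic cores, peritumoral edema, inter-scanner
variation, or segmentation error. A green pipeline on this cohort
demonstrates correctness of the machinery and sane statistical behavior —
not clinical performance on real scans.

## Selection and classification

Per training fold, a Welch two-sample t-test prefilter (default
$\alpha = 0.05$; if nothing survives, the single best feature is kept)
precedes one of seven rankers:

1. **rf** — random-forest permutation importance (out-of-bag accuracy drop;
   `ranger`), 500 trees.
2. **l0** — approximate zero-norm minimization via multiplicative
   rescaling: ridge-regularized linear margin refit, feature scales
   multiplied by $|w|$, collapse below tolerance eliminates a feature;
   ranked by elimination order.
3. **inf_fs** — infinite feature selection: path-energy row sums of
   $(I - rA)^{-1} - I$ on the dispersion/anti-correlation adjacency,
   $r = 0.9/\rho(A)$.
4. **fsv** — feature selection via concave minimization, approximated by
   successive linearization of $1 - e^{-a|w|}$ as penalty factors in
   weighted-$\ell_1$ logistic fits (glmnet, elastic mixing 0.95 so the
   per-round optimum is unique). Note the concave penalty *prefers*
   concentrating weight on one of two duplicated features; symmetry holds
   for the convex first round only.
5. **mrmr** — greedy max-relevance/min-redundancy with plug-in mutual
   information on tercile-discretized features; greedy depth defaults to
   50, remaining features appended by relevance.
6. **relieff** — ReliefF with 10 nearest hits/misses over all instances on
   min-max-scaled features.
7. **laplacian** — unsupervised Laplacian score on a 5-NN heat-kernel
   graph (rank ascending).

All score ties break by ascending feature index, so every ranking is a
deterministic full permutation. Classifiers: random forest (500 trees,
probability output), radial SVM (cost 1, $\gamma$ = inverse median squared
pairwise training distance), discrete AdaBoost.M1 over 200 depth-1 stumps
(implemented on `rpart`, since no AdaBoost implementation is available),
and LASSO-regularized logistic regression with the penalty chosen by inner
5-fold CV. The published study names these methods without
hyperparameters; the values above are this package's declared defaults,
all overridable.

## Evaluation protocol

Folds are stratified and sized within one lesion of each other; 210
lesions under 10-fold CV give train 189 / test 21 exactly. The default
grouping is lesion-level, replicating the original design — with the
acknowledged leakage risk that a patient's lesions can straddle folds;
patient-level grouping (`grouping = "patient"`) keeps each patient intact
and is the recommended mode for real data. Selection (prefilter + ranking)
is refit on every training fold; for each candidate feature count $k$ in
`k_grid` the classifier is refit on the top-$k$ features and scores its
test fold. Test scores are pooled across folds per $k$; the reported
optimal feature count maximizes pooled AUC (smallest $k$ on ties). Because
the published procedure for choosing the feature count is unstated, this
pooled-CV-argmax is a declared design decision, and its optimism risk is
the reason the permutation test reruns the *entire* procedure per
permutation. AUC is the Mann–Whitney pair-counting estimator (ties one
half, reported ×100); sensitivity/specificity/accuracy are taken at the
Youden-optimal threshold of the pooled scores. Size subgroups: small
(< 10 mm) under 10-fold CV, large (≥ 10 mm) under leave-one-out; the
boundary value 10 mm goes to the large group so the subgroups tile the
cohort.

The permutation test permutes labels (patient-level under patient
grouping), reruns the full cross-validated cell per permutation, and uses
$p = (1 + m)/(n + 1)$ with $m$ the number of permutations whose AUC is at
least the observed one — the "at least" is the conservative reading of a
formula stated with "higher".

## Problem sizes in the tests and acceptance script

The test suite and `scripts/acceptance.R` exercise the full pipeline at
the cohort scale the package emulates (about 61 patients / 210 lesions),
but economize elsewhere: the strong-effect recovery cell uses
`k_grid = {5, 10, 20, 30}`; the null-cohort calibration loop uses the
cheapest supervised cell (mRMR depth 10 + SVM, k = 10) with 99
permutations per seed and 20 fold/permutation seeds over one extracted
null cohort; selector-recovery simulations use 100 features at n = 200.
These sizes are the package's own benchmark configuration; the analysis
scripts under `analysis/` run the full 7 × 4 grid with a wider k grid and
default to 99 permutations at the observed optimal feature count (the
in-script constants raise this to the full 500-permutation protocol).

## Known limitations

* The bias-correction surrogate assumes smooth multiplicative shading;
  strong high-frequency nonuniformity would need a proper nonuniformity
  solver upstream.
* FSV and l0 selection are approximations of the cited formulations
  (successive linearization with a logistic surrogate; multiplicative
  rescaling) — exact LP/combinatorial solvers are out of scope.
* Lesion-level folding leaks patient identity across folds by design
  fidelity; use patient grouping for honest real-data estimates.
* The synthetic cohort's texture effect is stationary and isotropic;
  real intratumoral heterogeneity is neither.
* RFS filtering is 2D slice-wise (the standard definition of the bank);
  through-plane texture reaches the features only via the 3D GLCM/GLRLM.
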