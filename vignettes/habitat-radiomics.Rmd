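---
title: "Habitat radiomics on synthetic multiparametric MRI: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Habitat radiomics on synthetic multiparametric MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`habitatomics` implements a habitat-radiomics analysis for multiparametric
MRI of focal lesions: voxel-wise clustering of co-registered T1W, T2W and
ADC maps into intratumoral habitats, IBSI-style radiomic features per
habitat and for the whole lesion, staged feature selection, and logistic
classification evaluated with ROC/DeLong statistics, calibration and
decision curves. This vignette is the package's account of the underlying
models, the tunable parameters, the synthetic-data design, and the
numerical conventions — including what the passing test suite does and does
not establish about real clinical data.

## The analysis model

**Habitats.** Within a lesion mask, every voxel is a 3-vector of channel
intensities (T1, T2, ADC). After per-patient z-scoring of each channel
inside the ROI, the voxel × modality matrix is clustered with k-means
(k-means++ initialization, Lloyd iterations, 10 restarts, at most 300
iterations, relative inertia tolerance 1e-4). Without the z-scoring step,
the channels' arbitrary and very different numeric scales would decide the
metric; with it, each channel contributes equally.

**Choosing k.** For each patient the Calinski-Harabasz index

$$\mathrm{CH}(k) = \frac{B/(k-1)}{W/(n-k)}, \qquad
B = \sum_i n_i \lVert c_i - \bar c\rVert^2,\quad
W = \sum_i \sum_{x \in i} \lVert x - c_i\rVert^2$$

is evaluated for k = 2..10 and maximized (ties toward the smaller k).
Because habitats must be comparable across patients while the optimum is a
per-patient quantity, the cohort-level k is the mode of the per-patient
optima over the training patients, and every patient is then re-clustered
at that global k. A pooled-voxel clustering of the whole cohort would be
the alternative reading; the per-patient-with-modal-k design was chosen as
the minimal reconciliation of per-patient clustering with a single
cohort-wide habitat count, and the per-patient CH curves are returned for
audit (`cohort_k_selection()$curves`).

**Cross-patient habitat correspondence.** k-means labels are arbitrary, so
habitats are canonically ordered by *descending* mean ADC in raw units: the
last habitat index is always the lowest-ADC, most cellular compartment —
the slot where a malignant "triad" subregion (high T1, high T2, low ADC)
lands when present. Habitats smaller than 64 voxels are flagged excluded
and their feature rows set missing rather than merged away; missingness is
the least destructive choice and downstream model fitting simply drops
those patients for that region.

**Features.** 107 features per sequence: 18 first-order, 14 shape, 24
GLCM, 16 GLRLM, 16 GLSZM, 14 GLDM and 5 NGTDM, named
`{sequence}_{family}_{feature}`; with three sequences that is 321 per
region (whole lesion plus each habitat). Shape features are computed once
per region and repeated per sequence so the per-sequence accounting stays
at 107 even though they coincide on a shared grid.

**Selection and models.** Per region, features are reduced by (i) an
optional ICC(2,1) reproducibility screen across repeat delineations
(two-way random effects, absolute agreement; features with ICC < 0.75 or
undefined ICC dropped), (ii) Welch t relevance (used as an ordering, not a
cutoff), (iii) a Pearson redundancy filter that, for every pair with
|r| > 0.90, drops the member with the weaker relevance (ties to the
lexicographically later name; the drop set is computed from the full
correlation matrix so the result is column-order independent), (iv) greedy
mRMR (MID criterion — relevance minus mean redundancy — with mutual
information on 4-bin quantile-discretized features, keeping 30), and (v)
L1-penalized logistic regression with stratified 10-fold cross-validated
deviance, keeping the nonzero coefficients at `lambda.min`. Each stage's
survivors are nested in the previous stage's and recorded. A logistic
model per region is then fit by maximum likelihood on training-standardized
features (a small ridge penalty replaces the MLE, with a warning, under
separation or collinearity — routine at small n), with a stratified 5-fold
CV AUC and a Youden-optimal training threshold.

**Evaluation.** AUC uses the Mann-Whitney estimator with 0.5 tie credit
(identical to trapezoidal ROC integration). Confidence intervals and
paired model comparisons use DeLong structural components. Threshold
metrics (accuracy, sensitivity, specificity, PPV, NPV) carry Wilson score
intervals, the standard well-behaved choice at small n where Wald
intervals misbehave. Calibration is
summarized by equal-width bins plus the slope/intercept of a logistic
recalibration on the score logits. Decision curves report net benefit
$\mathrm{NB}(p_t) = \mathrm{TP}/n - (\mathrm{FP}/n)\,p_t/(1-p_t)$ against
treat-all and treat-none. Because the classifier is linear, SHAP
attributions are computed in closed form,
$\phi_j = \beta_j (x_j - \bar x_j)$ on the logit scale, with exact
additivity. The quantitative baseline is the mean in-lesion ADC with the
clinical decision threshold 1.29 (in units of 10⁻³ mm²/s; lower ADC =
more malignant).

## The synthetic cohort: what it emulates

No clinical images are distributed, so the generator is a first-class
module with planted ground truth. A lesion is an ellipsoid partitioned
into 1–3 contiguous azimuthal sectors, one per tissue signature, with
voxel counts proportional to the volume fractions (largest-remainder
rounding, exact to the voxel). Channel values are
`(signature mean + site shift) * (1 + bias field) + N(0, sd)`, on a grid
with a body-like background so bias estimation has anatomy to work with.
The default study conditions (`cohort_config()`, `pipeline_config()`):

* **Tissue signatures** `(T1, T2, ADC)` in arbitrary units for T1/T2 and
  10⁻³ mm²/s for ADC: viable stroma (1.6, 1.2, 1.35); cystic degeneration
  (0.9, 2.9, 1.60); a benign hypercellular/"hyaline" low-ADC class
  (2.1, 2.0, 0.90) — restricted diffusion *without* the triad's T1/T2
  hyperintensity; a hemorrhagic "red degeneration" focus (3.0, 1.3, 1.30) —
  high T1 *without* restricted diffusion; and the malignant triad
  (2.7, 2.6, 0.82), below the 1.29 ADC decision threshold. Within-habitat
  voxel noise SD is 0.15 per channel.
* **Composition.** Malignant lesions carry the triad at fraction
  0.3–0.5 plus stroma; benign lesions carry the hyaline class at 0.25–0.45
  (15% are single-region pure stroma). Either class additionally carries
  one degenerative extra — cystic with probability 0.45 or hemorrhagic
  with probability 0.45 — at fraction 0.15–0.35. The two mimics are the
  load-bearing design choice: benign lesions frequently contain *isolated*
  extreme signals (high T1 or high T2 or low ADC), so whole-lesion
  percentile and histogram features are confounded, while only malignant
  lesions contain all three *co-located* — exactly the contrast the
  low-ADC habitat isolates. Without them, every model saturates at
  AUC ≈ 1 and the comparison degenerates.
* **Between-patient variability.** Each patient's signature means are
  jittered by N(0, 0.30/0.30/0.09 per channel). This, not the voxel noise,
  creates class overlap: habitat-level means average over hundreds of
  voxels, so per-voxel noise alone would make classification trivial.
  With the jitter, the external AUCs land in the plausible clinical range
  (≈ 0.85–0.95 for the triad-habitat model, ≈ 0.75–0.85 for whole-tumor,
  ≈ 0.7–0.8 for mean ADC, averaged over replicate cohorts) instead of
  saturating.
* **Sites.** Three sites with additive per-channel shifts (site A none;
  site B +0.10/−0.05/+0.03; site C +0.25/+0.15/+0.08) applied before the
  bias field; training and test are a stratified 7:3 split of sites A+B
  pooled, site C is the external validation cohort.
* **Scale.** 12 + 12 + 16 patients by default (external share ≈ 0.4),
  lesion radii 7–9 mm on a 32³ grid at 1 mm spacing, bias amplitude 0.1.
  These sizes keep the multi-replicate study suites tractable on a single
  CPU; they are the package's simulation design, not clinical sample-size
  advice. At those radii every planted subregion comfortably clears the
  64-voxel floor.

What the generator does **not** emulate: realistic anatomy or lesion
shapes, Rician noise, motion/ghosting artifacts, registration error
between sequences (inputs are perfectly co-registered by construction),
DWI-to-ADC fitting, and scanner-specific contrast nonlinearities beyond an
additive shift. Passing tests therefore demonstrate the *pipeline's*
correctness and the internal consistency of the habitat argument under a
known mixture model — not clinical performance.

## Preprocessing choices

**Bias field.** Full N4 (multi-resolution B-spline histogram sharpening)
is not re-implemented; `correct_bias()` fits a polynomial of total degree
2 in normalized voxel coordinates to the log-intensities by least squares,
divides by the exponentiated field and restores the in-mask median. The
interface accepts any fitting mask so a full N4 implementation could be
swapped in. One lesson from the phantoms is worth recording: the fit must
use the *body* region, not the lesion ROI — a polynomial fitted inside the
ROI absorbs genuine tissue contrast (the habitats themselves) and destroys
the cluster structure it is supposed to protect (planted-truth ARI drops
from ≈ 1 to ≈ 0.2). The pipeline therefore fits over the whole
positive-intensity volume.

**Resampling.** Separable interpolation to 1 mm isotropic voxels:
Catmull-Rom cubic for images (order 1 and 0 available), nearest-neighbour
for masks and label maps, clamped borders, voxel centres at
`index * spacing` with 0-based indices. A 2 mm → 1 mm → 2 mm round trip on
a smooth phantom keeps the mean absolute error under 1% of the dynamic
range.

**Standardization.** In-ROI z-scoring uses the population SD (n
denominator), so `{1, 2, 3}` maps to `{-1.2247, 0, 1.2247}`.

## Numerical conventions and degenerate inputs

* Discretization: equal-width bins between the in-mask minimum and
  maximum, fixed *count* of 32 (configurable). The inputs' intensity
  scales are arbitrary, which makes a fixed bin *width* meaningless here;
  a fixed count is invariant to positive affine intensity transforms.
  The in-mask maximum is assigned to the top bin.
* GLCM/GLRLM aggregate by averaging per-direction feature values over the
  13 unique 3D directions (not by merging matrices); directions with no
  voxel pairs are skipped. GLSZM zones are 26-connected equal-level
  components. GLDM dependence is the count of 26-neighbours within
  gray-level tolerance 0, stored at dependence size d + 1 (the voxel
  itself counts), so an isolated voxel contributes at size 1. NGTDM
  excludes voxels with no in-region neighbour and returns the 1e6
  sentinel when the coarseness denominator vanishes.
* Degenerate regions: a constant region has entropy 0, uniformity 1,
  skewness/kurtosis 0, GLCM correlation 1, IMC1 0, MCC 1; regions of
  fewer than 2 voxels or with constant intensity get missing texture
  features while first-order and shape are still computed.
* Shape is voxel-based: volume = voxel count × voxel volume (the "mesh"
  volume coincides with it under this convention), surface by
  exposed-face counting, diameters as maximal pairwise distances between
  surface-voxel centres, axis lengths as 4√λ from the physical-coordinate
  covariance. Voxel-based surface and diameter values sit slightly above
  mesh-based tools' output; this is a documented convention, not a target
  of cross-tool agreement.
* k-means empty clusters are repaired by reseeding at the farthest point;
  fits are deterministic given the seed, and a single global seed expands
  deterministically into per-stage, per-patient seeds.
* Zero DeLong variance (perfect separation without ties) yields the
  degenerate point interval with a warning; identical score vectors give
  z = 0, p = 1 in the paired test.

## Open choices and how they were resolved

* Whether voxel channels are standardized before clustering, and whether
  clustering is per patient or pooled, are both unstated in the source
  methodology; per-patient clustering on z-scored channels is the
  default, and both alternatives remain available
  (`standardize_per_patient`, clustering the pooled matrix directly).
* The stage order of the feature reduction (ICC → univariate → Pearson →
  mRMR → LASSO), the Pearson threshold 0.90, the mRMR variant (MID,
  4-bin quantile MI, keep 30) and `lambda.min` are package choices where
  the methodology names only the ingredients; each stage's survivors are
  recorded so any alternative ordering can be audited.
* The ICC form is fixed to ICC(2,1) — two-way random effects, absolute
  agreement, single rater — the standard reproducibility choice for two
  readers.
* The operating threshold for tabulated metrics is the training Youden
  point; evaluation cohorts reuse the frozen training model and threshold
  (no refitting).

## Known limitations

Small default cohorts make individual-replicate AUCs noisy (the external
cohort has 16 patients); conclusions about model ordering are therefore
framed over replicates, not single runs. The ICC stage requires repeat
delineations, which `run_study()` does not simulate by default — the
screen is exercised with perturbed re-extractions in the unit tests and
available through `select_features(icc_tables = ...)`. Wavelet/LoG
filtered feature classes, 2D extraction, GMM or spatially regularized
clustering, and alternative classifiers are out of scope.
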