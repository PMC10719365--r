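---
title: "chromscope: methods, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chromscope: methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its science: the models and
procedures each stage implements, the parameters that matter and why they
have the defaults they do, what the synthetic generator does and does not
emulate, and the numerical and design choices made where the design was
genuinely open.

## The measurement model

PBMCs respond to circulating tumor-secretome signals with chromatin
reorganization. The package treats each nucleus as a 3D intensity field
sampled on an anisotropic voxel grid (0.09 µm laterally, 0.5 µm axially
by default) and reduces it to a "chrometric" profile: a fixed-order
vector of morphology, boundary-shape, DNA-intensity, image-moment and
heterochromatin/euchromatin descriptors, plus per-marker protein levels
and a γH2AX focus count. Patient-level inference is then a supervised
learning problem on these profiles, with the patient — not the cell — as
the unit of generalization.

## Segmentation

**2D candidates.** The DAPI stack is range-normalized (min–max per
stack; a constant image maps to zeros, the only sensible degenerate
choice), max-z projected, median-filtered and gamma-adjusted with
γ = 0.7 before Otsu thresholding and connected-component labeling.
Components are kept when their area lies in [800, 5000] px
([6.48, 40.5] µm² at the default pixel size) and they do not touch the
image border. The upper cap doubles as the merged-nuclei filter: two
touching PBMC nuclei exceed it, so no separate adjacency test exists.
The median filter's footprint is a radius-1 cross (5 pixels) with
reflective edge padding — small enough to preserve nuclear boundaries,
large enough to kill single-pixel noise; the filter size is a free
choice and the package fixes it once.

**Per-stack vs per-plane normalization** was an open choice; the package
normalizes per stack, because per-plane normalization would rescale the
axial intensity profile that the Chan–Vese stage relies on.

**3D refinement.** Each candidate's bounding box is padded by 12 px
(≈ 1 µm; clipped at borders and flagged rather than discarded, so
downstream QC sees the evidence), cropped across all channels and z.
Background is cleared outside the convex hull of the candidate mask
dilated 12 times with a 3×3 cross — an approximate whole-cell region
that keeps the perinuclear Lamin and surface-marker signal. The DAPI
channel is additionally re-cleared against a hole-filled Otsu mask of
its own projection. The 3D mask comes from a Chan–Vese level set on the
re-normalized DAPI crop.

The Chan–Vese implementation is the morphological formulation: boundary
voxels switch phase by the sign of λ₁(I−c₁)² − λ₂(I−c₂)², followed by a
majority-vote smoothing pass that plays the role of the curvature term.
Fixed choices: checkerboard initialization (period 5 voxels — robust and
initialization-free in the sense that no seed point is needed),
(λ₁, λ₂) = (1, 2), a hard cap of 300 iterations and a convergence
tolerance of 1e-3 on the fraction of voxels changing per iteration. The
heavier outside weight (λ₂ = 2) penalizes background impurity and suits
a bright nucleus on a cleared background. After evolution the largest
connected component is kept (one nucleus per crop by construction),
and QC requires ≥ 400 voxels (1.62 µm³) and a z-height — occupied planes
× axial step, inclusive — of 2.5–10 µm. Height outside that window
indicates an axially cut-off or overlapping nucleus. On synthetic
ellipsoids the recovered masks overlap the ground truth with Jaccard
≈ 0.99.

**Cell masks** are nuclear masks dilated 12 px laterally and 2 planes
axially (box structuring element), exploiting the ball-like shape of
PBMCs.

## Chrometric features

- **Morphology**: volume (voxels × voxel volume), projected area, height,
  2D concavity (1 − area/hull area, exact 2D convex hull), a 3D
  solidity-type concavity computed with *slice-wise* 2D hulls (a
  z-convex approximation; no 3D hull dependency), and principal-axis
  aspect/elongation from the eigenvalues of the voxel-coordinate
  covariance computed in physical units, so the 5.6× axial anisotropy
  does not distort the axes. Single-plane masks get `NA` 3D concavity.
- **Boundary curvature**: the contour is resampled to 128 equal
  arc-length points and low-passed by truncating its Fourier series to
  8 harmonics before differentiating. Raw finite differences on a
  rasterized contour measure the pixel staircase (curvature errors of
  several 1/µm); nuclear shapes are low-order, so an 8-harmonic contour
  keeps the real shape modes (the generator plants modes 2–4) while
  suppressing the staircase. Mean |κ| of a rasterized circle is then
  recovered within 2%. Reported: mean |κ|, SD of κ (the boundary
  "variability"), max |κ|, in 1/µm.
- **Intensity**: mean, SD, skewness, excess kurtosis, nine deciles, and
  Shannon entropy (bits) of a 64-bin in-mask histogram.
- **Moments**: normalized central moments to order 3 and the seven Hu
  rotation invariants of the masked projected intensity.
- **HC/EC**: in-mask two-class Otsu partition — parameter-free and
  consistent with the pipeline's other thresholding — giving HC volume,
  HC/EC ratio, HC volume fraction and HC intensity fraction; the
  partition conserves volume exactly, and a uniform nucleus is flagged
  `NA` rather than given an arbitrary split.

The exact feature catalog is a package decision: it covers everything
the analyses use (≈ 45 features across the five categories listed by
`feature_dictionary()`), not an attempt at parity with any external
feature library. Marker quantification uses the *nuclear* mask for all
markers including Lamin A/C; Lamin is perinuclear, so the 12 px crop
padding retains its signal, but a sensitivity analysis with the expanded
cell mask is a reasonable extension.

## γH2AX foci

Projection and mask are max-z projected; the projection is
range-normalized so the count is invariant under affine intensity
rescaling; the threshold is mean + 2.5 SD with both statistics over
*in-mask* pixels — computing them over the whole crop would be biased by
the zeroed background, which is the one place the procedure is
underdetermined. SD = 0 (flat signal) returns zero foci. Components
< 4 px are dropped, touching foci are split by a watershed on the
intensity landscape (neighborhood radius 2 px, tolerance 0.05 on the
[0,1] scale — maxima closer in height than that merge to one seed, which
handles plateaus), and sub-4 px fragments are dropped again. Well
separated planted spots are recovered exactly in 100/100 random
placements.

## Cell typing

Area-normalized total marker intensity per nucleus, gated per patient
sample by a two-component Gaussian mixture with unequal variances. The
fit uses `mclust`'s deterministic model-based initialization; the
threshold is the equal-posterior crossing between the component means
(solved by root-finding on the log posterior ratio), which honors
unequal weights and variances where a midpoint would not. Gates are
flagged unreliable — and their samples excluded from typing — when the
fit fails or the separation |µ₂−µ₁|/max(σ) is below 0.5. Values exactly
at the threshold are negative (deterministic tie rule). Subset labels
combine the CD4/CD8 gates; CD3 status is kept separate. Gate recovery on
planted mixtures is within ±2% absolute across positivity fractions
0.1–0.9.

## Analysis layer

- **Pruning**: features correlated |r| > 0.8 with any other feature are
  removed greedily in fixed column order, keeping the earlier member —
  deterministic where the rule itself does not specify which member to
  drop. Pairs at exactly 0.8 are kept (strict inequality, with a 1e-10
  floating-point guard). Constant columns are removed first with a
  warning (undefined correlation).
- **Balancing**: equal random per-patient-sample cell counts, seeded;
  units below the floor are excluded. This is also where the
  "stratified" aspect of the cross-validation lives: equal
  representation is enforced in the input rather than re-weighted per
  fold.
- **LOPO CV**: one fold per patient; the forest (500 trees by default,
  √p candidate features per split, unlimited depth, per-fold seeds)
  never sees the held-out patient's cells. Per-fold balanced accuracy,
  sensitivity/specificity for binary tasks, and the average of
  row-normalized confusion matrices — each row averaged over the folds
  whose test set actually contained that class, since a held-out
  patient carries a single class in condition-type tasks. By default a
  patient holding cells of more than one class is an error (label
  leakage for condition tasks); time-point tasks, where every patient
  legitimately spans all classes, set `allow_multiclass_patients = TRUE`.
- **Majority vote**: a patient's call is its modal predicted class; exact
  ties break by class order and are flagged ambiguous.
- **Permutation baseline**: labels are permuted across the whole table
  (not within patient — the permuted world should destroy the
  feature–label link entirely), the full LOPO procedure is re-run 10
  times, and the observed per-fold accuracies are compared with the
  pooled null per-fold accuracies by a two-sided Wilcoxon rank-sum
  test. On balanced k-class null cohorts the null mean sits within
  Monte-Carlo error of 1/k.
- **Ablations**: training-set subsampling by patients (k per class) or
  by cells (per-patient count `max(1, floor(p·n))`), 10 repetitions.
- **Screens**: two-sided Welch t-tests per feature (pairwise for > 2
  groups), BH adjustment across the entire screen (screen-wide rather
  than per-pair — one multiple-testing family per question), adjusted
  p < 0.05, star coding ns/*/**/***/****.
- **Embeddings**: exact O(n²) t-SNE (implemented in-package: perplexity
  calibration by bisection, early exaggeration, momentum gradient
  descent; deterministic under seed; intended for the few-thousand-cell
  QC scale), LDA, or PCA, for visual batch-effect control.

A known statistical limitation, deliberate and documented rather than
patched: the Welch screen tests cells, not patients. With patient-level
random effects, cells are not exchangeable across conditions and a
cell-level test is anticonservative — exactly the pathology the
patient-held-out classifier avoids. The calibration suite therefore
checks screen quietness on *exchangeable* null cohorts (patient effect
SD = 0); on clustered nulls the screen's false-positive rate is a
property of the method, not of this implementation.

## The synthetic generator

`generate_nucleus_image()` emulates what the analyses assume: an
anisotropically voxelized ellipsoid (lateral semi-axes ≈ 2.2 ± 0.2 µm,
axial ≈ 1.8 ± 0.15 µm — a resting PBMC nucleus of ≈ 15 µm² projected
area and 3.6 µm height, comfortably inside all QC windows) with angular
boundary modulation (modes 2–4), a smoothed Gaussian-random-field DAPI
texture plus discrete high-intensity blobs grown to a target
heterochromatin fraction (default 25%), Poisson-many Gaussian foci
(default rate 2) with ≥ 6 px separation, a rim-weighted Lamin channel,
uniform-in-cell CD levels set by the planted subset label, additive
background (0.04) and Gaussian noise (SD 0.02) on a [0,1] scale, in a
150 × 150 px × 21-plane field (a 13.5 µm square crop). Condition effects
are multiplicative dials on volume, HC fraction, focus rate and boundary
irregularity; patient effects are multiplicative log-normal with SD 0.05.
Ground truth is recorded before noise and matches the rendered geometry
exactly in the noise-free limit.

What it does **not** emulate: the microscope PSF and axial blur,
chromatic aberration, photobleaching, spectral spillover between
channels, touching/overlapping cells, debris, and the long-tailed
texture of real chromatin. Passing tests therefore demonstrate that the
algorithms do what they claim on images with known truth — correct
thresholds, exact conversions, recoverable planted effects — not that
any particular accuracy figure transfers to any particular real
dataset.

`simulate_feature_cohort()` draws feature tables directly from the
hierarchical model (patient × condition × cell) so the analysis layer
can be exercised and calibrated at cohort sizes — thousands of cells,
dozens of seeded replicates — where rendering every nucleus would be
disproportionate. The image generator remains the ground truth for the
extraction stages; the feature simulator is the package's choice of
instrument for the statistical layer, and the problem sizes used in the
tests and the acceptance script (e.g. 5 patients × 50–60 cells per
condition, 150–200 trees, 10 permutations, 12 rendered nuclei, 100
focus placements) were chosen once as the smallest designs at which the
expected behaviors are unambiguous.

## Degenerate inputs and tie rules, collected

- constant image → range-normalizes to zeros; Otsu errors
  ("degenerate histogram"); 2D segmentation returns no candidates.
- flat in-mask γH2AX (SD = 0) → zero foci.
- uniform nucleus → HC/EC features `NA`.
- single-plane mask → 3D concavity `NA`, height still computed.
- gate value exactly at threshold → negative.
- majority-vote tie → first class in level order, flagged ambiguous.
- watershed seed ties → resolved by the deterministic label order of the
  underlying transform.
- correlation exactly 0.8 → both features kept.

## Limitations

Beyond the generator's realism limits above: touching-nucleus splitting
is out of scope (the size cap discards merged objects instead); the 3D
concavity is slice-wise rather than true-3D; Chan–Vese runs on
intensity only (no edge term); the classifier family is fixed to random
forests with conventional hyperparameters — the package measures
separability under a standard learner rather than maximizing accuracy;
and accuracies reported elsewhere on external patient datasets are not
reproduction targets of the test suite, which is built entirely on
synthetic ground truth.
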