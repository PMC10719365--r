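# chromscope

Chromatin imaging biomarkers from 3D nuclear images of peripheral blood
mononuclear cells (PBMCs).

## The problem

Tumors secrete signaling molecules into the bloodstream. Circulating
PBMCs sense these secretome signals and respond with chromatin
reorganization, so the nuclear architecture of PBMCs from a routine blood
draw carries information about whether a donor harbors a tumor, which
tumor group, and how a therapy is progressing. `chromscope` turns
multi-channel 3D confocal z-stacks of immunostained PBMC nuclei (DAPI +
γH2AX + Lamin A/C + CD3/CD4/CD8) into quantitative "chrometric" profiles
and patient-level classifications, for imaging groups and computational
biologists who want a desk-testable, fully synthetic-data-verifiable
implementation of this kind of pipeline.

## What it computes

**Segmentation.** 2D nucleus candidates from the DAPI channel (max-z
projection → median denoise → γ = 0.7 gamma adjustment → Otsu threshold →
connected components, keeping areas in [800, 5000] px = [6.48, 40.5] µm²
and dropping border-touching objects), then background-cleared 3D crops
(12 px padded boxes, clearing outside the convex hull of the 12× cross-
dilated mask) refined by a 3D Chan–Vese level set with (λ₁, λ₂) = (1, 2)
and ≤ 300 iterations. Quality control keeps masks with ≥ 400 voxels
(1.62 µm³) and z-height in [2.5, 10] µm. Cell masks are the nuclear masks
expanded 12 px laterally and 2 planes axially.

**Chrometric features (~45 per nucleus).** Morphology (volume, projected
area, height, 2D/3D concavity, principal-axis shape), boundary curvature
(mean/SD/max of κ along a Fourier-smoothed contour), DNA-intensity
statistics (moments, deciles, entropy), image moments (normalized central
moments and the seven Hu invariants), and heterochromatin/euchromatin
content by in-mask Otsu partitioning.

**γH2AX foci.** Per-nucleus DNA-damage focus counts: threshold the
normalized max-z projection at mean + 2.5 SD (in-mask statistics), drop
components < 4 px (0.032 µm²), split touching foci with a watershed
seeded at local intensity maxima, drop fragments < 4 px again.

**Cell typing.** Per-sample two-component Gaussian-mixture gates on
area-normalized CD3/CD4/CD8 intensities; thresholds at the
equal-posterior crossing between the component means; CD4/CD8 subset
labels and relative abundances.

**Analysis layer.** Correlation pruning (|r| > 0.8), patient-balanced
sampling, leave-one-patient-out random-forest cross-validation reporting
balanced accuracy `mean over classes of per-class recall`, patient-level
majority voting, a 10× label-permutation chance baseline with a two-sided
Wilcoxon rank-sum comparison, patient-count and cell-count ablation
curves, Gini importance ranking, and a Welch *t* / Benjamini–Hochberg
biomarker screen with the usual star coding.

**Synthetic data.** `generate_nucleus_image()` / `generate_cohort()`
render ellipsoidal textured nuclei with planted foci, rim-weighted Lamin,
bimodal CD markers, condition effects and patient random effects — every
stage of the pipeline is testable against known ground truth without any
microscopy download. `simulate_feature_cohort()` draws feature tables
from the equivalent statistical model for analysis-layer work.

## Worked example

Render a synthetic nucleus, segment it, and profile it:

```r
library(chromscope)
res   <- generate_nucleus_image(synthetic_spec(foci_rate = 3), seed = 42)
stack <- res$stack
d     <- dim(stack$voxels)
stack$voxels[1,,,] <- range_normalize(array(stack$voxels[1,,,], d[2:4]))
recs  <- segment_stack(stack)
prof  <- assemble_profile(recs[[1]])
prof[, c("volume_um3", "height_um", "hc_volume_fraction", "foci_count")]
#>   volume_um3 height_um hc_volume_fraction foci_count
#> 1     40.022       3.5              0.331          1
```

The planted truth for this seed is volume 40.45 µm³, HC fraction 0.296
and 1 focus — the pipeline recovers the volume within 1%, the HC
fraction within a few percent (texture noise), and the focus count
exactly.

Classify a synthetic two-condition cohort (5 patients per condition,
60 cells each, planted tumor effects on volume, HC fraction and focus
rate):

```r
tab  <- simulate_feature_cohort(n_patients_per_condition = 5,
                                cells_per_patient = 60, seed = 1)
bal  <- balance_sample(prune_correlated(tab), seed = 1)
cv   <- lopo_cv_rfc(bal, "condition", config = rf_config(ntree = 200), seed = 1)
cv
#> Leave-one-patient-out RF cross-validation ('condition', 2 classes, 10 folds)
#> balanced accuracy: 0.928 (+/- 0.061)
#> sensitivity 0.937 | specificity 0.920 (positive = 'tumor')

permutation_baseline(bal, "condition", n_perm = 10,
                     config = rf_config(ntree = 200), seed = 1, observed = cv)
#> Permutation baseline: 10 permutations, mean balanced accuracy 0.496
#> observed 0.928 vs null, two-sided Wilcoxon rank-sum p = 2.06e-07

gini_ranking(cv, top_n = 3)
#>              feature importance   category
#> 1         foci_count  0.4573171 dna_damage
#> 2         volume_um3  0.1638895 morphology
#> 3 hc_volume_fraction  0.0955063      hc_ec
```

The classifier separates the conditions far above its own permutation
null, and the three planted-effect features top the importance ranking —
the same features the Welch/BH screen flags.

A thin command-line wrapper over the same functions ships in
`inst/cli/chromscope.R` (`simulate`, `extract`, `analyze` subcommands,
YAML config).

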