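---
title: "Edema radiomics on T2-weighted breast MRI: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edema radiomics methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question the pipeline answers

Peritumoral edema — the bright halo around or beyond a breast tumor on
T2-weighted MRI — is a marker of aggressive disease. This package asks a
quantitative version of that observation: does the *texture* of the
segmented edema carry information about histological prognostic factors
(histological type, nuclear grade, ER, PgR, Ki-67) beyond what the
clinician already records? The unit of comparison is a paired contrast of
two cross-validated random-forest classifiers per label: one trained on
11 human-recorded ("semantic") descriptors, one on those plus 242
radiomic features of the edema ROI, evaluated on identical folds.

## ROI refinement: the voxelized 3D convex hull

Manual edema segmentations have jagged edges and concavities wherever the
edema abuts tissue of similar T2 signal. `convex_hull_refine()` replaces
the ROI with the voxelization of the convex hull of its voxel centers:
every voxel whose center lies inside or on the hull (inclusive tolerance
`1e-9` voxel units) is retained. This removes segmentation deformities
and deliberately annexes a thin rim of perimeter tissue, which may itself
be informative.

Two choices here were genuinely open and are fixed as package policy:

* **Index space, not millimetre space.** The hull is computed on voxel
  indices, making the operation invariant to the (anisotropic) voxel
  spacing and bit-for-bit reproducible across scanners. A physical-space
  hull would differ on anisotropic grids; nothing in the underlying claim
  depends on that distinction.
* **Rasterization rule.** Membership is tested at voxel centers with a
  small inclusive tolerance, so boundary centers are kept ("slightly
  expand" rather than shrink).

Internally the hull is rasterized by polytope slicing: each z-level
cross-section equals the 2D convex hull of the input points at that level
plus the crossings of all segments that span it; degenerate (collinear or
coplanar) inputs reduce to point-on-segment / point-in-polygon tests.
Tests verify superset, idempotence and convexity properties on random
masks and exact agreement with an exhaustive Caratheodory point-in-hull
oracle on small grids.

## The 253-feature bank

All texture is computed at native 16-bit depth — no gray-level rebinning
— and intrinsically in 3D. The bank is frozen, name by name, in
`feature_manifest()` and in `inst/extdata/feature_manifest.json`:

| block | count | names |
|---|---|---|
| semantic | 11 | `sem_age` … `sem_edema_type` |
| first-order | 12 | `fo_mean` … `fo_rel_max_energy` |
| LBP-TOP | 48 | `lbp_<variant>_<stat>` |
| 3D GLCM | 182 | `glcm_<dir>_<stat>` |

**First-order (12).** Statistics of the exact-intensity histogram
(identity binning over 0..65535): mean, SD, skewness, excess kurtosis,
energy, entropy (bits), maximum bin probability, its position, energy in
a window around the maximum, occupied range, number of relative maxima,
and energy around the relative maxima. Conventions the bare names leave
open, fixed here: moments are population moments over bin probabilities
(equal to voxel moments under identity binning); skewness and kurtosis
are defined as 0 for a constant ROI; kurtosis is *excess* kurtosis; peak
windows have half-width `w = 5` gray levels (configurable — the value is
arbitrary and only needs to be held fixed across a study); relative
maxima are plateaus of the nonempty-bin sequence strictly above both
nearest nonempty neighbours, a plateau counting once and a missing
neighbour counting as lower.

**LBP-TOP (48).** Radius-1, 8-neighbour local binary patterns in each of
the three orthogonal planes, four code variants (`basic` 256 codes,
rotation-invariant `ri` 36, uniform `u2` 59, `riu2` 10). The three
per-plane code histograms are concatenated (not summed — summing would
discard the plane identity, which is exactly the orientation information
the three-plane construction exists to keep) and summarized with the same
12 statistics. Ties (neighbour equal to center) set the bit; neighbour
validity requires the 3×3 ring to lie in the *grid*, not the ROI, since
the hull-expanded ROI intentionally includes rim tissue. The four
variants are the standard LBP family; which four an implementation uses
is a choice, and these are the ones with established definitions.

**3D GLCM (182).** Seven statistics (autocorrelation, covariance,
inertia, absolute inertia, inverse inertia, energy, entropy) per each of
the 26 *directed* unit displacements — a direction and its opposite are
distinct tables, which is what makes the count 26 rather than 13. Pair
tables are held sparsely over the observed gray pairs; the 65536²
dense matrix is never materialized, which is how full-bit-depth
co-occurrence stays tractable. An ROI too thin to contain any pair along
some direction contributes seven zeros with a warning, so every feature
is defined (and finite) down to single-voxel ROIs.

## Labels and thresholds

`dichotomize()` maps raw pathology to the five binary targets: IDC vs
ILC, G1+G2 vs G3 (minority grouped against the rest), ER and PgR at a
configurable percentage cut (default 1%), Ki-67 at a configurable cut
(default 14%). The receptor and Ki-67 conventions genuinely vary between
laboratories (10% and 20% are common alternatives), so no single value is
hard-coded; the synthetic generator draws raw percentages that
dichotomize identically under either convention, making downstream
results threshold-robust by construction.

## Model pipeline

Per label, `crossval_evaluate()` runs stratified 10-fold CV. Inside each
training fold only, `best_first_select()` performs forward best-first
search: subset merit is the mean AUC of a `ranger` random forest under
internal stratified 5-fold CV (3-fold in the scaled-down acceptance
runs); search stops after 5 consecutive non-improving expansions
(improvement threshold 1e-4); ties resolve to the earlier feature in the
canonical order, making the search deterministic under its seed. An
optional univariate screen (`screen_top`) restricts the candidate pool to
the features with the largest training-fold |AUC − 0.5| before the search
— computed inside the training fold, so it cannot leak test information.

Held-out probabilities are pooled into a single ROC (one AUC and one
confusion matrix per experiment, not fold averages) and thresholded at
0.5. Ratios with empty denominators are reported as 0 and flagged; this
is what makes an all-negative classifier on an imbalanced label read
sensitivity 0%, specificity 100%, PPV 0% rather than NaN. AUC is the
normalized Mann–Whitney statistic (ties count 1/2) and is tested against
a brute-force pairwise oracle.

Random-forest defaults are 100 trees and √p split candidates; the
original analysis environment's defaults are not portable, so all
hyperparameters live in `eval_config()`/`select_config()`. No cap is
placed on selected-set size by default (the forest performs its own
internal feature weighting); `max_size` can impose one.
`compare_configurations()` runs both arms on identical folds and seeds so
per-label deltas are paired. Whole-cohort "signature" selection (as
opposed to in-fold selection) can be obtained by calling
`best_first_select()` on the full feature table; the cross-validated
reports always use in-fold selection, which is the bias-free protocol.

## The synthetic cohort

Real patient images for this design are not publicly distributable, so
`generate_cohort()` emulates the study population: 127 lesions; edema
types at 49/20/13/18% (peritumoral, pre-pectoral, subcutaneous, diffuse);
positive-class prevalences ILC 13.4%, G3 47.2%, ER+ 79.5%, PgR+ 36.2%,
Ki-67-high 66.1%; age ≈ N(54.9, 11) within 28–90; diameters ≈ lognormal
with median 19 mm in 9–60 mm; menopause, family history, hormone
therapy, margins and kinetic-curve frequencies at their reported
marginals. Each lesion's phantom is a stationary Gaussian random field
(white noise convolved with an isotropic Gaussian kernel, correlation
length 1.5 voxels) — background mean 200, SD 40; edema mean 600, SD 80 —
with a jagged ellipsoidal edema ROI (relative boundary jitter 0.15, the
kind of ragged manual segmentation the hull refinement exists to clean).
The intensity scale is an artifact choice: no quantitative T2 intensity
distributions were available to match, so only the orderings (edema
brighter than background) and the 16-bit range are meaningful.

Class signal is planted only inside the edema ROI. `texture_effect`
scales the edema noise SD for positive-class lesions (one unit = ×1.5).
The amplitude route was chosen deliberately: rank-based LBP codes are
invariant to intensity scaling, while co-occurrence statistics track
local difference amplitudes directly, so the planted signal is
specifically GLCM-detectable — matching the pipeline property that
wrapper selection under a planted texture effect should favour GLCM
features. (A correlation-length shift, the other natural knob, is seen
*more* strongly by LBP than by GLCM and would invert that property.)
`semantic_effect` mildly shifts age and lesion size for positive lesions,
so the qualitative headline — combined beats semantic-only where texture
signal exists — is reproducible in direction. Prevalences are exact
Bernoulli draws, so empirical rates calibrate to specification within
binomial error (property-tested at n = 2000).

What the phantom does *not* emulate: breast anatomy, coil profiles,
bias fields, partial-volume edges, DCE kinetics, inter-reader
segmentation variability. Passing tests therefore validate the
*machinery* (geometry, features, selection, evaluation, calibration),
not clinical performance on real images.

## Problem sizes and numerical choices

Test and acceptance runs scale the imaging problem down, as a package
choice, to: 20³–24³ voxel grids (64³ default elsewhere), 50–100 trees,
3-fold internal selection CV with a univariate screen of width 25,
cohorts of 127 (structure checks, null calibration — 20 seeds in the
test suite, 10 in the reproduction script) and 60 (signal recovery,
10 seeds). Null calibration is run without in-fold selection:
selection inside training folds cannot bias held-out AUC, and dropping it
makes the 20-seed calibration cheap. The null-calibration acceptance
check compares each label's AUC *averaged over the 20 seeds* against
0.5 ± 0.1: a single-seed CV AUC at n = 127 has SD ≈ 0.06 under the null,
so any per-seed band of ±0.1 would fail by chance alone across 100
label-seed draws.

Other numerics: hull membership tolerance 1e-9 voxel units; GLCM pair
keys packed as `i·65536 + j` (exact in doubles); FFT-based circular
convolution for the Gaussian field (the field is standardized afterwards,
so kernel truncation never enters); seeds derived from one master seed
via a seeded `sample.int`, keeping every derived seed below 2³¹.

## Known limitations

* The voxelized hull is exact for hull *membership at voxel centers*;
  no sub-voxel surface is represented.
* LBP uses the 8 grid neighbours without circular interpolation; on
  strongly anisotropic grids the XZ/YZ planes mix physical scales, which
  mirrors computing on native anisotropic stacks and then letting
  selection discard orientation-sensitive features that do not help.
* Best-first search cost grows with the candidate pool; at the full 253
  features without screening it is a long computation, which is why
  `screen_top` exists.
* Synthetic cohorts calibrate marginal structure, not the joint
  dependence of semantic descriptors observed clinically (only the mild
  planted couplings are present).
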