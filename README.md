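# edemaradiomics

Radiomic analysis of peritumoral edema on T2-weighted breast MRI, for
imaging researchers who want to test whether edema *texture* predicts
histological prognostic factors beyond the clinical picture.

Edema on T2-weighted images — peritumoral, pre-pectoral, subcutaneous or
diffuse — accompanies aggressive breast cancers. Given a binary edema
segmentation and the T2 volume, this package:

1. **Refines the ROI** with a voxelized three-dimensional convex hull,
   removing segmentation deformities and annexing a thin rim of
   perimeter tissue (`convex_hull_refine()`).
2. **Extracts a frozen bank of 253 features** per lesion
   (`extract_features()`): 11 semantic descriptors (age, menopausal
   status, family history, hormone therapy, location, stadiation,
   margins, dimensions, morphology, kinetic curve, edema type); 12
   first-order statistics of the exact-intensity histogram (2¹⁶ bins, no
   gray-level reduction); 48 LBP-TOP features (radius-1, 8-neighbour
   local binary patterns in the three orthogonal planes, four variants ×
   the same 12 histogram statistics); and 182 3D-GLCM features — seven
   co-occurrence statistics per each of the 26 directed unit
   displacements at interpixel distance 1, on sparse full-bit-depth pair
   tables.
3. **Compares classifiers** per dichotomous label (IDC/ILC, G1+G2/G3,
   ER±, PgR±, Ki-67 low/high): stratified 10-fold cross-validation with
   best-first wrapper feature selection (random-forest evaluator) nested
   inside each training fold, semantic-only vs semantic + edema
   radiomics on identical folds (`compare_configurations()`). Reports
   pool held-out predictions into one ROC: AUC (Mann–Whitney form),
   accuracy, sensitivity, specificity, PPV, NPV.

A synthetic-cohort generator (`generate_cohort()`) reproduces the
reference population structure (127 lesions, edema types 49/20/13/18%,
ILC 13.4%, G3 47.2%, ER+ 79.5%, PgR+ 36.2%, Ki-67-high 66.1%) with a
controllable texture signal planted inside the edema ROI, so the whole
pipeline is testable without patient data.

## Worked example

Simulate a 40-lesion cohort with a texture effect planted on the grading
label, extract features and run the paired comparison:

```r
library(edemaradiomics)

spec <- cohort_spec(
  n_lesions = 40, grid_shape = c(24, 24, 24),
  texture_effect = c(histology = 0, grading = 1, er = 0, pgr = 0, ki67 = 0),
  seed = 42)
cohort <- generate_cohort(spec)

cohort$volume[[1]]
#> <voxel_volume 24x24x24 (z,y,x), spacing 3.5x1.05x1.05 mm, range [44, 685]>
mask_summary(convex_hull_refine(cohort$mask[[1]]), spacing = spec$spacing)
#> # A tibble: 1 × 8
#>   n_voxels volume_mm3    z0    z1    y0    y1    x0    x1
#>      <int>      <dbl> <int> <int> <int> <int> <int> <int>
#> 1      541      2088.     8    19     8    20     9    19

features <- extract_features(cohort)   # 40 x 254 (lesion_id + 253 features)

cfg <- eval_config(n_folds = 5, trees = 50,
                   select = select_config(trees = 25, internal_folds = 3,
                                          screen_top = 15))
cmp <- compare_configurations(
  features, dplyr::select(cohort, dplyr::starts_with("label_")),
  cfg = cfg, seed = 1)
cmp
#> <edema_comparison: 5 labels, paired folds, seed 1>
#>   histology  AUC 0.457 -> 0.674 (delta +0.217)
#>   grading    AUC 0.588 -> 0.968 (delta +0.380)
#>   er         AUC 0.650 -> 0.469 (delta -0.182)
#>   pgr        AUC 0.593 -> 0.467 (delta -0.127)
#>   ki67       AUC 0.528 -> 0.484 (delta -0.044)
```

Reading the output: the first AUC of each row is the semantic-only
classifier, the second adds the edema radiomics. The grading label —
the only one with a planted texture effect at this seed — gains 0.38
AUC; the no-signal labels fluctuate around chance, which is exactly the
calibration a null label should show at n = 40. `glance(cmp)` returns
the full metric table (AUC, accuracy, sensitivity, specificity, PPV,
NPV per label and arm, with paired deltas), `tidy()` the long form, and
`ggplot2::autoplot(cmp)` a paired AUC dot plot. Per-report objects
support `tidy()`, `glance()` and `autoplot()` (pooled ROC curve) too.

Disk-based runs (`run_simulate()`, `run_extract()`, `run_evaluate()`)
read and write NIfTI volumes plus CSV/JSON tables; a thin CLI wrapper
lives at `inst/scripts/edemaradiomics-cli.R` with `simulate`, `extract`
and `evaluate` subcommands.

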