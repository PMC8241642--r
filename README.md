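# petsym

Symmetry-driven analysis of spatially normalized 3D brain FDG-PET for
temporal lobe epilepsy (TLE). The healthy brain is approximately
left-right symmetric in glucose uptake, while the epileptic focus is a
*unilateral* hypo- or hypermetabolic abnormality with an unclear
boundary. `petsym` turns that observation into three linked analyses:

1. **Radiomics symmetricity diagnosis.** Each subject's bilateral
   temporal ROIs are described by a frozen 386-feature vector (6
   intensity + 36 texture + 344 Coiflet-1 wavelet features). The
   symmetricity vector `d_i = |f_i^left − f_i^right|` feeds a cohort
   matrix that is column-wise z-scored; features are grouped into k = 10
   clusters by hierarchical clustering (average linkage, correlation
   distance 1 − |r|) and the per-cluster maximizer of the Fisher
   inter-intra class variance ratio
   `FICVR = |μ_p − μ_c| / sqrt(σ_p² + σ_c²)` is selected; a
   cross-validated L2-penalized logistic regression classifies patient
   vs. control.
2. **Pair-of-cubes (PoC) Siamese focus localization.** Hemispheres are
   split at the mid-grid plane and tiled with n³ cubes; each cube is
   paired with its mirrored contralateral cube. A weight-sharing twin 3D
   residual network embeds both cubes (1024-entry embeddings) and scores
   `p = sigmoid(FC(|embed(a) − embed(b)|))`; scores of all PoCs are
   assembled into a probability heat map, thresholded, and lateralized
   against a normative control template.
3. **Asymmetric-index grading.** The predicted focus is graded by the
   per-slice asymmetric index
   `AI = 2 (SUVR_ipsi − SUVR_contra) / (SUVR_ipsi + SUVR_contra)`:
   *severe* iff |AI| > 0.15 on ≥ 3 consecutive slices, else *mild*;
   hypo- vs hypermetabolism by the sign of AI.

A synthetic phantom generator (mirror-symmetric brain, planted
unilateral foci with controllable contrast, 4.4 mm PSF blur, additive
noise) stands in for a clinical cohort and makes the whole pipeline
testable end to end. See `vignettes/petsym-methods.Rmd` for the models,
parameter choices, and limitations.

## Worked example

Generate one phantom patient (30% hypometabolic focus, left temporal
lobe), extract bilateral features, and grade the planted focus:

```r
library(petsym)

cfg  <- phantom_config(focus_contrast = -0.3, focus_side = "left", seed = 42)
case <- generate_case(cfg)
case
#> <phantom_case> severe left focus, delta = -0.30, expected AI = -0.297

zm      <- to_zmap(case$volume)
f_left  <- extract_all(zm, case$roi_left)    # 386 features
f_right <- extract_all(zm, case$roi_right)
d       <- symmetricity_vector(f_left, f_right)
round(sort(d, decreasing = TRUE)[1:2], 2)
#>  glzsm.LZHGE wav.dec2.glcm.cluster_prominence
#>     20361.20                         16997.07

prof <- ai_profile(case$volume, case$focus_mask)
head(prof, 3)
#>   slice      ai n_vox
#> 1    12 -0.2702    21
#> 2    13 -0.2909    37
#> 3    14 -0.3112    57
grade_metabolic(prof)
#> <metabolic_grade> severe hypometabolism (|AI| > 0.15 on >= 3 consecutive slices: yes)
```

The planted contrast of −0.30 is attenuated by partial-volume blurring
to an expected AI of −0.297; the measured per-slice AI tracks it and the
rule grades the focus severe hypometabolic, matching the planted truth.

The full pipeline — cohort generation, PoC extraction with
subject-disjoint splits, Siamese training, heat maps, localization,
lateralization, grading, and the Jensen-Shannon + logistic-regression
baseline — runs from one call (a few minutes on one CPU at the default
desk scale of 20 patients + 6 controls, tiny tower, 16³ cubes):

```r
report <- run_pipeline(list(seed = 1))
report
#> <eval_report>
#>   mean Dice (patients):   0.740
#>   PoC AUC (Siamese/test): 0.983
#>   PoC AUC (JS-LR):        0.871
#>   polarity accuracy:      100%
#>   severity accuracy:      95%
```

Mean Dice is the overlap of the localized focus with the planted mask
over patients; the PoC AUCs compare the Siamese classifier with the JS
divergence baseline on held-out cubes; polarity/severity accuracies
compare the AI grading of the *predicted* focus against the analytic
planted truth.

A thin command-line interface wraps the same functions
(`inst/exec/petsym`): `petsym preprocess`, `petsym phantom`,
`petsym features`, `petsym grade`, `petsym run`.

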