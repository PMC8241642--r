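---
title: "Symmetry-driven analysis of brain FDG-PET: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Symmetry-driven analysis of brain FDG-PET: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In temporal lobe epilepsy (TLE), interictal FDG-PET typically shows a
*unilateral* metabolic abnormality — most often hypometabolism, sometimes
hypermetabolism — with an unclear boundary that is hard to delineate
visually. The healthy brain, by contrast, is approximately left-right
symmetric in its glucose uptake. `petsym` operationalizes this observation
three ways:

1. **Diagnosis** — quantify how asymmetric a subject's bilateral temporal
   lobes are in a high-dimensional radiomics feature space, and classify
   patient vs. control from that asymmetry signature.
2. **Localization** — compare every image cube with its mirrored
   contralateral cube through a weight-sharing twin ("Siamese") 3D
   residual network, and assemble the pair scores into a voxel-level
   abnormality heat map.
3. **Grading** — measure the metabolic level of the localized focus with
   the asymmetric index and classify it into one of four levels
   (severe/mild x hypo-/hypermetabolism).

All inputs are assumed spatially normalized to a left-right symmetric
template; registration itself is out of scope. The package convention is:
first voxel axis = left-right axis, mirror plane = mid-grid plane, an odd
left-right extent is padded by one zero slab before splitting.

## Intensity standardization (Z-maps)

Uptake values are not comparable across subjects without dose/weight
calibration, so every volume is standardized within its brain mask:
`z = (v - mu) / sigma` with population sigma (`to_zmap()`). Voxels outside
the mask are set to 0. The transform is idempotent and makes the
within-mask distribution mean-0/SD-1, which both the radiomics distances
and the network inputs rely on. An alternative reading of the Z-map
transform — Fisher's z (arctanh) applied to intensities rescaled into
(-1, 1) — is available as `to_zmap(method = "arctanh")`; it changes only
the marginal distribution, not the left-right comparability, and the
default was chosen because voxelwise standardization is the established
meaning of a PET Z-map.

## The 386-feature radiomics registry

`extract_all()` produces, per region of interest (ROI), a frozen-order
vector of

* 6 intensity features (mean, population variance, skewness, excess
  kurtosis, energy, natural-log histogram entropy over `G = 32` bins),
* 36 texture features: 10 histogram statistics, 10 GLCM statistics
  (13 unique 3D directions at distance 1, accumulated symmetrically into
  one matrix), 5 Amadasun-King NGTDM features (26-neighborhood), and 11
  GLZSM zone-emphasis features (zones = 26-connected equal-level
  components),
* 344 wavelet features: a single-level periodized 3D Coiflet-1
  decomposition of the zeroed, canonically oriented, even-padded ROI
  bounding box into 8 subbands; per subband the 6 intensity + 36 texture
  features on the mask-restricted coefficients plus one relative subband
  energy (43 x 8).

The exact identity of the 36 texture and 344 wavelet features is a
registry choice of this package (`feature_registry()`); the block sizes
6/36/344 and named features such as HGZE and LZHGE are fixed. The tenth
histogram feature is the mean absolute deviation rather than a second
histogram entropy, because an exact duplicate column would be degenerate
under the column z-scoring that follows. Gray levels default to `G = 32`
with equal-width per-ROI binning (top bin inclusive).

Two properties matter downstream and are enforced by construction and by
tests: every feature is invariant to translation of the ROI and to
left-right mirroring. Texture statistics get this from symmetric direction
and neighborhood sets; the wavelet block gets it by flipping the ROI
bounding box into a canonical left-right orientation before the DWT
(mirrored ROI contents therefore produce bit-identical coefficients).
The periodized DWT is orthonormal, so subband energies sum to the input
energy exactly (a Parseval test guards this).

## Symmetricity diagnosis

For each subject the symmetricity vector is `d_i = |f_i_left -
f_i_right|` over the 386 features of the two temporal ROIs; stacking
subjects gives the symmetricity matrix, which is column-wise z-scored
(population SD; zero-variance columns are zeroed with a warning).

Feature selection groups the 386 columns into `k = 10` clusters by
average-linkage hierarchical clustering under correlation distance
`1 - |r|` — absolute correlation groups redundant features regardless of
sign, which is the right notion when one representative per cluster will
be kept — and selects per cluster the feature maximizing the Fisher
inter-intra class variance ratio `FICVR = |mu_p - mu_c| /
sqrt(sigma_p^2 + sigma_c^2)` (population variances; ties go to the lowest
registry index; a zero-variance pair with differing means scores `Inf`).

The classifier is an L2-penalized logistic regression (fixed penalty 1.0,
solved by Newton/IRLS in `ridge_logistic()`) under seeded, stratified
10-fold cross-validation; features are standardized inside each training
fold only, so no statistics leak from held-out subjects. Baselines
(`diagnosis_baselines()`) use the same harness: every single feature
alone, all features, and PCA-reduced features (components fitted per
training fold). With all components kept and fold-level centering only,
the PCA model is exactly the all-features model (ridge is rotation
invariant); this is used as a correctness check rather than a baseline.

## Pair-of-cubes Siamese localization

Z-maps are split at the mid-grid plane and the right half is flipped so
homologous voxels share indices. Cubes of `n^3` voxels tile each
hemisphere (stride grid, final cube edge-aligned; cubes under 5% brain
coverage dropped), and each cube is paired with the congruent mirrored
cube — a pair-of-cubes (PoC). A PoC is labeled abnormal when the focus
mask occupies at least 0.5% of either cube footprint (inclusive).

The scoring model embeds both cubes with one shared-parameter 3D residual
tower (structurally one parameter set, so weight sharing is exact), takes
the elementwise absolute difference of the two 1024-entry embeddings, and
maps it through a fully connected layer and sigmoid to `p in (0, 1)`.
Two contracts follow directly from this architecture and are tested
bit-exactly: `score(a, b) = score(b, a)`, and every self-paired cube
scores the same constant `sigmoid(b_head)` (the zero-difference
baseline).

The full-scale tower is an 18-weighted-layer residual network (stem
convolution, four stages of two residual blocks with 64/128/256/512
channels, global average pooling, linear map to 1024); a reduced "tiny"
preset (4/8 channels, one block per stage, 16^3 input) is the desk-scale
default used throughout the tests. No normalization layers are used: at
these depths plain He-initialized residual blocks train stably and keep
the forward pass fully deterministic. Training is plain SGD (learning
rate 0.01, weight decay 0.005, batch 128, 16 epochs) on weighted binary
cross-entropy with inverse-class-frequency sample weights; training-set
positives can additionally be augmented (shared-transform axis flips,
radial warp `r -> r(1 + alpha r^2)` with `|alpha| <= 0.05`, global
intensity scale/shift — all label-preserving because both cubes receive
the identical transform). After each epoch the validation AUC is logged;
the returned model is the best-validation-AUC epoch, with equal AUCs
tie-broken by validation loss (without the tie-break, training that
saturates AUC early returns a probability-uncalibrated model). The
backward pass of the convolution kernels is verified against central
finite differences in the test suite.

Splits are subject-disjoint 60/20/20 (stratified by patient/control):
cube-level splitting would leak a subject's anatomy between train and
validation and inflate the validation AUC.

### Heat maps, localization, lateralization

`siamese_heatmap()` scores every PoC and writes `p` into the voxels of
*both* cube footprints, averaging overlaps — so the map is
mirror-symmetric by construction, bounded in [0, 1], zero outside the
brain. Training uses stride `n/2`; inference uses stride `n/4`, because
the localization resolution is set by the origin grid and a sub-cube
focus is unresolvable at half-cube sampling. The map carries a coverage
array; voxels only partially covered by the cube grid inherit single-cube
scores and are excluded by the adaptive localizer.

`localize_focus()` thresholds the map. The adaptive default is
`baseline + 0.9 * (max - baseline)`: a voxel's averaged response
approaches the map maximum only when essentially *all* cubes covering it
are scored abnormal, so the 0.9 fraction implements near-unanimity of the
covering cubes with 10% slack for cubes that barely graze the focus. If
the map maximum is within 0.01 of the zero-difference baseline, no focus
is declared (this margin exists to return an empty mask on symmetric
null inputs; the trained probability scale is compressed near the
baseline, so larger absolute floors would be meaningless). The default
component rule is "bilateral": the largest 26-connected component plus
its mirror twin — which is what the symmetric map actually supports.

A pair score cannot tell *which* side is abnormal: `|e_a - e_b|` is
unchanged when the hemispheres swap. Lateralization therefore needs
outside information, and `lateralize_focus()` uses the cohort's controls:
it keeps the hemisphere part of the mask whose Z-map deviates more (mean
absolute difference) from a normative template (voxelwise mean of control
Z-maps). This mirrors standard normative-comparison practice in PET and
is exact on phantoms.

As a classical baseline, `js_lr_baseline()` scores each PoC by the
Jensen-Shannon divergence (base-2, 64 shared bins over the pooled range)
between its two cubes' intensity histograms and cross-validates a
logistic regression on that single feature.

## Asymmetry-index grading

For the predicted (lateralized) focus, `ai_profile()` computes per axial
slice `AI = 2 (SUVR_ipsi - SUVR_contra) / (SUVR_ipsi + SUVR_contra)`
between the in-slice mask voxels and their mirrored counterparts, on the
raw uptake volume (not the Z-map, whose zero mean would make SUVR
undefined). The SUVR reference is the whole-brain mean — atlas-free and
scale-invariant, configurable to a user-supplied reference mask.
`grade_metabolic()` declares *severe* iff `|AI| > 0.15` (strict) on at
least 3 consecutive profile slices, else *mild*; polarity is the sign of
the mean AI (an exactly zero mean defers to the largest-|AI| slice).

## The phantom generator

`generate_case()` emulates the study conditions the framework targets,
not realistic anatomy: an exactly mirror-symmetric ellipsoidal brain with
a bright cortical-like shell (values around 100 arbitrary uptake units);
mirrored lateral-inferior "temporal" ROIs; an optional spherical focus
whose pre-blur intensity is scaled by `1 + delta` (`delta < 0` hypo,
`> 0` hyper), placed at a seeded location wholly inside the stated-side
ROI; Gaussian point-spread blurring at FWHM 4.4 mm (the center-of-field
resolution of the clinical scanner setting the framework's context); and
additive post-blur Gaussian noise with SD 5% of the within-brain mean.
Background and lesion increment are blurred separately and the background
re-symmetrized, so a `delta = 0` case is *exactly* mirror-symmetric —
making the null checks (zero symmetricity vector, constant heat map,
zero AI) exact rather than tolerance-based. Per-case seeds derive
deterministically from the cohort seed; identical seeds give
bit-identical cases.

Defaults, chosen once as the package's study conditions: 48 x 56 x 48
voxels at 3 mm; contrast magnitude uniform in [0.15, 0.45] with 80%
hypometabolic (the dominant TLE presentation); focus radius 14 mm. The
radius keeps the lesion-diameter-to-cube-edge ratio of the desk-scale
configuration (28 mm vs 16-voxel = 48 mm cubes) comparable to the
clinical geometry of lobar abnormalities against full-size 96 mm cubes;
a focus much smaller than one cube is unresolvable by any
footprint-based heat map. A lobulated (three-sphere) focus mode exists
for irregular-shape stress tests.

Severity ground truth is *analytic*: blurring recovers only a fraction
`R` of the planted contrast (the mean of the blurred focus indicator
over the focus — the standard partial-volume recovery coefficient), so
the expected focus asymmetry is `AI = 2 delta R / (2 + delta R)`,
thresholded at 0.15 like the grading rule. Truth is therefore independent
of the image-based per-slice measurement it is compared against.

What the phantom does *not* emulate: real anatomy and its
normal-variant asymmetries, Poisson/reconstruction noise correlations,
scanner-specific resolution anisotropy, registration error, and
multi-focal disease. Passing the phantom suites shows the machinery is
correct and self-consistent under the stated model; it does not certify
clinical performance.

## Problem sizes and numerical choices

The test and acceptance workloads use the tiny tower with 16^3 cubes on
48 x 56 x 48 phantoms: a 20-patient/6-control cohort for end-to-end
localization (training stride 8, inference stride 4, 16 epochs), a
30-phantom cohort (20/10) for the feature-selection count, and 4 x 4 x 4
ROIs for the brute-force texture oracles. These sizes were chosen so the
full suite exercises every stage at desk scale. Further conventions:
population moments throughout (declared once, used by intensity features,
FICVR, and the column z-scoring); half-open top-inclusive quantization
bins; `0 log 0 = 0` in all entropies; empty-vs-empty Dice defined as 1
(both methods agree there is no focus), empty-vs-nonempty as 0; GLCM
correlation of a constant ROI defined as 1; NGTDM coarseness sentinel
1e6 for a zero denominator; ridge-logistic Newton iterations capped at
100 with tolerance 1e-10.

## Known limitations

* The Siamese score is side-blind; lateralization requires controls (or
  an external normative template). Without controls the output is the
  bilateral candidate pair.
* The adaptive localization threshold declares a focus whenever the map
  response exceeds the baseline by 0.01; on noisy control cases this
  yields false-positive candidate regions. Patient-vs-control
  discrimination is the job of the diagnosis classifier, not the
  localizer.
* Heat-map resolution is bounded by the cube size and origin stride;
  foci well below the cube scale are systematically over-segmented.
* The 386-feature registry is this package's concrete instantiation of
  the 6/36/344 layout; other instantiations exist.
* Training is single-threaded CPU; the full 48^3 preset is provided for
  completeness but is not exercised by the desk-scale suites.
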