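---
title: "Methods: SUV quantification, organ segmentation and tissue classification in petrad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SUV quantification, organ segmentation and tissue classification in petrad}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Whole-body FDG-PET shows every tissue with high glucose uptake. In
oncology that is a nuisance: brain, myocardium, kidneys and bladder
routinely light up as brightly as tumor, so a simple standard-uptake-value
(SUV) threshold cannot by itself tell tumor from physiology. `petrad`
implements an automated pipeline that (i) converts activity images to SUV,
(ii) isolates and partitions all high-uptake regions, (iii) summarises
each region with radiomics features, and (iv) labels each region as brain,
heart, left/right kidney, bladder or tumor with a random forest, under the
anatomical constraint that a scan contains at most one of each normal
organ. Because clinical PET volumes cannot ship with a package, a
synthetic whole-body phantom generator reproduces the geometry and uptake
statistics the pipeline assumes, so every stage is testable end to end.

# SUV conversion

Measured activity concentration $C(x,y,z)$ (Bq/mL) is converted to the
body-weight SUV

$$\mathrm{SUV}(x,y,z) \;=\; \frac{C(x,y,z)}{2^{-t/T_{1/2}}}\cdot\frac{W}{D},$$

with $W$ the body weight in grams, $D$ the injected dose in Bq, $t$ the
injection-to-scan delay and $T_{1/2}$ the radionuclide half-life (F-18:
109.77 min). The decay factor refers the dose to scan time; the result
carries g/mL. The conversion is exact arithmetic and is verified against
an independent scalar evaluation to relative $10^{-12}$.

Weight is accepted in kg (and dose in MBq) only at the I/O layer
(`read_pet_nifti()`); the core works in grams and Bq so the unit
convention is explicit.

# Resampling, smoothing, thresholding

Scanners deliver anisotropic grids, so volumes are first resampled to an
isotropic 5 mm voxel by separable cubic (Keys, $a=-1/2$) interpolation,
which reproduces constant and linear fields exactly in the interior;
interpolation undershoot below zero is clamped. The SUV image is then
smoothed with a normalised isotropic 3-D Gaussian ($\sigma$ = 1 voxel =
5 mm by default, support truncated at $4\sigma$, replicate boundary).
Smoothing serves two purposes: it suppresses voxel noise and it evens out
intra-organ uptake gradients (grey vs white matter, left ventricle vs
atria) that would otherwise fragment an organ at the threshold step.
Finally the smoothed image is binarised at SUV $\ge 3$ (inclusive), the
conventional floor for FDG-avid tissue.

Two conventions worth noting:

* the smoothing kernel is the standard normalised Gaussian
  ($\sigma^2$ in the exponent, $(2\pi)^{3/2}\sigma^3$ normaliser) — an
  unnormalised kernel would not preserve constant fields, contradicting
  its denoising purpose;
* the threshold applies to the *smoothed* SUV, which is also the
  substrate for all later SUV sampling, so segmentation and features see
  one consistent image.

# Watershed segmentation

The high-uptake mask is partitioned per 26-connected component by a
marker-based watershed on the inverted smoothed SUV. Markers are h-maxima
(peaks at least $h$ = 1 SUV above their saddle, computed by grayscale
reconstruction of $f-h$ under $f$, 6-connected); the flood claims mask
voxels in order of descending smoothed SUV through 6-connected steps.
This splits touching organs with distinct peaks (bladder against an
adjacent pelvic tumor) where plain connected components cannot, while a
single-peak component is returned whole. Determinism matters for
testability: all ordering ties break towards the smaller linear voxel
index, which makes the flood reproducible and lets the test suite compare
it voxel-for-voxel against an exhaustive brute-force flood on small
grids.

Each region is then closed with a 1-voxel ball structuring element
(cavities from cold organ cores are filled; closing never removes
voxels; voxels contested between regions go to the region with the higher
mean SUV), and regions below 4 mL are dropped — the detection floor below
which lesions are not reliably identified at this grid resolution.
A user-supplied label map can replace the automatic segmentation
(`segment_pet(manual_labels=)`), the escape hatch used clinically for
super-scans with diffuse skeletal uptake.

# Radiomics features

Each region is summarised by 28 core features, optionally extended by 34
texture features.

**First-order (14).** Energy, entropy, excess kurtosis, maximum, mean,
mean absolute deviation, median, minimum, range, RMS, skewness, SD,
uniformity, variance — computed on the region's smoothed SUV samples.
Moments use the population ($n$-denominator) convention; kurtosis is
excess kurtosis; a constant region takes skewness = kurtosis = 0,
entropy = 0, uniformity = 1. Entropy and uniformity need a histogram:
SUVs are discretized into 32 equal-width bins spanning the region's own
range (config-exposed; the choice is an editorial default, as is common
for these feature sets).

**Shape (14).** Volume (mL), surface area, surface-to-volume ratio,
sphericity $\pi^{1/3}(6V)^{2/3}/A$, spherical disproportion
$A/(4\pi R_{eq}^2)$, compactness 1 $V/(\sqrt\pi A^{3/2})$, compactness 2
$36\pi V^2/A^3$ (identically sphericity cubed), maximum 3-D diameter, and
six spatial descriptors: the SUV-weighted centroid normalised to $[0,1]$
within the scan bounding box (patients differ in height, so only relative
location is comparable across scans; an absolute-mm variant would not
transfer between cohorts), and the unit principal axis of the voxel
coordinate covariance with the sign fixed to a non-negative Z component.
"Maximum radius vector" is ambiguous in the field's usage; the principal
eigenvector is the implemented reading, being rotationally meaningful and
stable.

*Surface area estimation.* Rather than triangulating the binary mask
(no 3-D marching-cubes implementation exists in the installed R stack,
and a hand-ported case table is a liability), surface area uses the
coarea identity: the mask is Gaussian-smoothed ($\sigma$ = 1 voxel) and
$A=\int\lVert\nabla f\rVert\,dV$ is accumulated over the field. The
estimator is exact for planar interfaces and has relative error of order
$(\sigma/R)^2$ for curvature radius $R$; a digitized radius-10-voxel
sphere lands within 1% of $4\pi r^2$, well inside the
$[0.95, 1.05]$ sphericity band the tests assert. Sharp edges (voxel
cubes) are smoothed by any such estimator, which is why the closed-form
shape indices are additionally exposed as `shape_indices(V, A)` and
verified against exact-surface oracles. The maximum 3-D diameter is the
largest pairwise distance among surface-voxel centres (candidates pruned
by 200 projection directions before the exact pairwise pass).

**Texture (34).** A symmetric gray-level co-occurrence matrix (GLCM,
23 statistics) and a gray-level run-length matrix (GLRLM, 11 statistics),
both at voxel distance 1, pooled over the 13 unique 3-D directions and
normalised once. The exact 34-name list is a documented editorial
default (23 GLCM + 11 GLRLM); catalogues in the literature differ
slightly in which co-occurrence statistics they include, and the count
here is fixed so the feature-table layout is frozen. A constant region
collapses the matrices to one cell: contrast-type features are 0, GLCM
energy 1, and undefined correlation-type features are reported as 0 with
a warning. Both matrices are validated against brute-force pair/run
enumeration oracles on small regions.

# Classification

A random forest of 50 CART trees (Gini, unlimited depth, $\sqrt p$
candidate features per split, bootstrap size $n$ — none of which the
field's convention fixes differently) is trained on the labelled feature
table; "equally weighted features" is implemented as: no scaling, no
per-feature priors (forests are scale-invariant anyway). Class priors
are uniform in the sense that no rebalancing is applied. With the 34
texture features the tree count is doubled to 100. Out-of-bag error is
recorded on the fitted model.

Per scan, predicted class probabilities (tree-vote fractions) are turned
into labels under the **sole-occurrence constraint**: each normal organ
may label at most one region, tumor any number. The labeling maximises
$\sum_r \log(p_{r,c(r)}+\varepsilon)$, $\varepsilon=10^{-9}$, solved
*exactly* by dynamic programming over the $2^5$ subsets of used normal
classes — regions in row order, each choosing tumor or an unused organ.
Exactness makes the contract testable against exhaustive enumeration of
all feasible labelings (the test suite does this on 1000 random
probability matrices). The constraint is enforced at prediction only,
not during training. Regions that in reality belong to none of the six
classes (thyroid, salivary glands) are still forced into one of the six
labels; an explicit reject option is deliberately not enabled by
default, matching the closed-set design.

# Evaluation

Segmentation quality is reported as sensitivity, specificity, precision,
accuracy, Dice and Jaccard from voxelwise TP/FP/FN/TN; specificity uses
the full field-of-view denominator (hence its characteristically high
values on whole-body grids). Degenerate conventions: two empty masks
score 1 everywhere; an empty reference with non-empty prediction scores
sensitivity 0 with a warning. Volume concordance between automatic and
reference volumes is an ordinary least-squares fit (slope, intercept,
$R^2$). Feature discrimination uses Welch two-sample t-tests per feature
per class pair (the unequal-variance form is the safer default when only
"t-test" is specified; a pooled-variance flag exists), with no
multiple-testing correction by default (a Benjamini–Hochberg adjustment
can be applied downstream via `p.adjust`); zero-variance
degeneracies take p = 0 (means differ) or 1 (means equal). A ranked
top-5 table per tissue scores each feature by its worst p-value over
that tissue's pairs, so listed features separate the tissue from *every*
other class.

# The phantom

`phantom_spec()` encodes the study conditions:

* **Grid**: 140 x 70 x 340 voxels at 5 mm — a torso-scale whole-body box.
* **Organ volumes** (mean ± SD mL, drawn log-normal, floored at 8 mL so
  structures stay resolvable at 5 mm): brain 1468.37 ± 266.15, heart
  197.59 ± 125.63, left kidney 30.70 ± 22.61, right kidney 31.20 ± 22.85,
  bladder 118.94 ± 153.07; tumors 193.90 ± 394.46 (log-normal with its
  heavy right tail, truncated at 1 mL).
* **Presence**: brain and bladder always; heart 0.48, left kidney 0.91,
  right kidney 0.86; tumor count Poisson(1.386) truncated at 4, giving
  P(at least one tumor) = 0.75. These rates reproduce the observed
  per-scan visibility of each tissue; presence probability and SUV level
  are deliberately independent knobs rather than modelling why a tissue
  is invisible.
* **Uptake**: organ SUV means 5.5–6 with SD 0.5–1 (truncated at 4.2).
  No authoritative per-organ SUV table exists for this setting, so the
  values are chosen once on physical grounds: with background SUV 1 and
  threshold 3, an organ at SUV ~5 puts the smoothed half-maximum
  crossing at its anatomical boundary, the regime the smoothing
  discussion assumes; well above ~7 the thresholded region visibly
  dilates, well below ~4.5 it erodes.
* **Partial uptake**: hearts show apex-only uptake with probability 0.25
  (the inferior third of the organ); kidneys collecting-system-only
  uptake with probability 0.25 (a central co-ellipsoid, ~22% of organ
  volume). The ground-truth label map records the *active* sub-volume —
  the segmentation target is FDG-avid tissue, not anatomy — while the
  manifest keeps the anatomical volume and the mode for stratification.
* **Geometry**: ellipsoids with per-organ axis ratios and ±2% anchor
  jitter; tumors at uniform random trunk/extremity positions (z in
  [0.05, 0.80] of the body box — the cranial vault is occupied by
  brain), with a 20 mm bounding-sphere clearance between structures so
  that smoothing halos cannot merge regions. Anatomical realism beyond
  ellipsoids is deliberately out of scope: the features that carry the
  classification (volume, compactness, centroid) do not need it.
* **Noise and dosimetry**: additive Gaussian noise, SD 0.1 SUV (10% of
  background); weight ~ N(54, 15) kg clamped to 25–100; dose
  5.55 MBq/kg; 60 min uptake; F-18 half-life. The activity field is
  back-converted so `convert_to_suv()` recovers the designed SUV field.
  Poisson counting physics, scanner PSF and reconstruction are not
  modelled.

What the phantom does *not* emulate — non-uniform intra-organ uptake
textures, bowel/brown-fat confounders, bed-position stitching artefacts,
inter-scanner resolution differences — bounds what green tests mean:
they demonstrate correctness of the algorithms and recoverability of the
design parameters, not clinical-grade accuracy on patient scans.

# Problem sizes and determinism

The test-suite and acceptance-script experiments use two independently
seeded 30-scan cohorts at the default grid (train on one, test on the
other), 20 scans for segmentation quality medians, all matched tumors
(typically 60–80) for volume concordance, 1000 random probability
matrices for the assignment oracle, and 1000 null replicates for t-test
calibration — sizes at which every check completes in minutes on one
CPU while keeping binomial/OLS noise well inside the asserted margins.
All randomness flows from explicit integer seeds: phantom cohorts derive
per-scan seeds from a master seed, and forest training takes its own
seed, so every reported number is bit-reproducible.

# Known limitations

* The watershed requires peaks separated by more than `h` in SUV;
  touching organs with near-equal plateaus merge. The usual remedy
  (local Otsu re-thresholding) is intentionally not implemented.
* The coarea surface estimator under-reports sharp-edged surfaces (it
  smooths corners); for the near-ellipsoidal regions the pipeline
  produces this bias is negligible, and the closed-form index helpers
  are available when an exact surface is known.
* Organ SUV distributions and partial-uptake fractions are stylised;
  classifier accuracies measured on the phantom characterise the
  pipeline under its own design assumptions, not clinical performance.
* DICOM series input is not provided (no DICOM reader in the supported
  dependency set); NIfTI plus explicit acquisition metadata is the
  supported input path.
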