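---
title: "Quantifying normal bone-marrow FDG uptake: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying normal bone-marrow FDG uptake: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmpet)
```

## The measurement problem

Bone-marrow FDG uptake is diffuse, large-volume and age-dependent, which
makes the usual tumor-oriented SUV workflow (draw a small ROI, read off a
maximum) a poor fit. The approach implemented here instead treats the whole
spine-plus-pelvis marrow cavity as one organ: the cavity is segmented from
the CT half of a PET/CT exam, the PET volume is masked with it, every voxel
is converted to SUL (SUV normalized by lean body mass rather than body
weight, appropriate because FDG is dosed per kilogram but fat takes up
little tracer), and the masked intensity histogram is summarized.

The per-subject readout is: marrow volume, SUL\_max, SUL\_mean, first-order
histogram entropy, the percentage of marrow voxels above the mediastinal
blood-pool reference (%Higher volume), and an ordinal reference-region
score of the Th11 vertebral marrow against mediastinum and liver.

## Pipeline stages and their assumptions

**Bone extraction** (`segment_bone`) thresholds the CT at `hu_threshold`
(default 150 HU, a conventional cortical-bone cutoff), closes the result
with a one-voxel ball to seal thin cortex gaps, fills enclosed cavities
slice-wise, and drops 26-connected components smaller than
`min_component_voxels` (default 50, enough to reject isolated
calcifications while keeping vertebra-sized structures). The fill step is
what turns a thresholded cortical *shell* into the bone *envelope*; without
it there is no cavity for the subsequent erosion to expose. This assumes
cortical bone surrounds the marrow in-plane — true for vertebral bodies
and iliac wings at PET-matched CT resolution.

**Cortex erosion** (`erode_cortex`) removes `erosion_pixels` (default 2)
one-pixel margins with a 4-connected cross on each axial slice. Erosion is
2D by default because the voxels are anisotropic (4.11 mm in-plane vs 5 mm
axial): a 3D erosion would remove disproportionate axial extent. A
`three_d` flag provides the 3D variant for isotropic data. The structuring
element and dimensionality are deliberately configuration-exposed: neither
is uniquely determined by clinical practice.

**Manual-correction emulation** (`apply_exclusions`) subtracts
caller-supplied regions (labeled masks or boxes) and logs the removed voxel
count — the programmatic stand-in for an operator deleting thyroid, dental
metal or vascular calcifications from the bone mask.

**Quantification** (`quantify_subject`) composes SUL conversion, marrow
statistics, entropy, reference means, %Higher volume and the Th11 score.
Numerical conventions, chosen once and kept:

* Histogram entropy uses `entropy_bins` (default 64) equal-width bins on
  `[0, max(values)]`, log base 2, occupied bins only. With 64 bins the
  value is bounded by 6 bits, and typical marrow histograms land in the
  4–4.5 bit range; binning metadata is reported alongside the value since
  entropy is only comparable at matched binning.
* %Higher volume uses a strict inequality against the mediastinal ROI
  *mean* (the natural symmetric choice alongside the scoring rule; the
  comparison statistic is configuration-visible in the result record).
* The Th11 score resolves boundary ties downward: equality with a
  reference assigns the lower score ("above" is read strictly). Only
  scores 2–4 are emitted; grades 1 and 5 have no operational definition in
  a reference-region-only setting. Inverted references (liver below
  mediastinum) are an error, not a score.
* Marrow volume is voxel count × exact voxel volume from the spacing — no
  mesh estimate, no partial-volume weighting.
* Negative PET voxels (reconstruction artifacts in real data) are clamped
  to zero at construction with a logged count, keeping SUL non-negative.
* Empty masks are errors everywhere except IoU, where empty∩empty is
  defined as 1.0 (and warned about): two sessions that both found nothing
  did agree.

**Reproducibility.** The ICC form is two-way mixed effects, absolute
agreement, single measurement — the standard choice for one reader
performing repeated sessions — computed from the ANOVA mean squares and
reported with its model tag so alternative forms can be compared.

**Cohort statistics** are base-R tests behind a uniform report interface:
pooled-variance t (Welch optional) and Mann–Whitney U between sexes,
Pearson/Spearman correlations (Spearman forced for the smoking indicator),
one-way ANOVA across score groups, and chi-square without continuity
correction when all expected counts are ≥ 5, Fisher's exact otherwise (the
applied rule is recorded). The multivariate regression mirrors the
two-stage clinical convention: predictors enter when their univariate
correlation has p < 0.05, and the selected set is always logged. Sample
(n−1) standard deviations are used throughout; no multiple-testing
correction is applied by default (a deliberate match to common practice in
descriptive cohort tables), though `p.adjust` can be applied downstream.

## What the phantom emulates — and what it does not

The generator (`generate_phantom`, `generate_cohort`) exists to make every
stage testable against exact ground truth, so geometry is blocky and
parametric rather than anatomical: 12 contiguous vertebral cuboids and two
pelvic blocks, each a marrow core inside an in-plane cortical shell
(default 2 voxels — matched to the erosion depth because both model the
same physical cortex), plus cuboidal mediastinal and liver reference
regions. The cortical shell has no axial end-plates: the erosion that
defines the measured cavity is in-plane, so in-plane shells are the
geometry whose ground truth the pipeline can recover exactly. Defaults put
the male marrow at about 13,500 voxels (≈1140 cm³) on the
4.11 × 4.11 × 5 mm grid, with women at 0.888 linear scale and a 4%
log-normal per-subject size jitter.

Marrow uptake is a linear age model, `a_sex + b_age (age − 55)` with
defaults `a_M = 0.79`, `a_F = 0.75`, `b_age = −0.004` per year: uptake
declines with age and men exceed women. Within-marrow dispersion is
Gaussian with SD 0.12 at age 55, declining by 0.0015 per year — younger
marrow is modeled as more heterogeneous, which is what makes histogram
entropy fall with age. Reference levels default to mediastinum 0.95 and
liver 1.30 SUL. Reconstruction is emulated by 5 mm FWHM Gaussian smoothing
followed by additive Gaussian noise with SD `noise_sd × sqrt(signal)`
(variance proportional to signal, as in reconstructed images — not raw
Poisson counts). The PET volume is stored in Bq/ml through the inverse SUL
relation, so the quantification stage genuinely re-derives SUL from dose
and lean body mass.

The cohort simulator draws sexes ≈57:41 M:F, per-sex Gaussian ages
(55.5 ± 14.2 / 56.3 ± 18.9 y) held to the 20–80 y enrollment range by
boundary clamping (clamping rather than rejection keeps the per-sex mean at
its nominal location; the resulting boundary atoms are the price, and they
are small for men), heights and BMI tuned so implied lean body mass
averages ≈52.6 kg (men) and ≈34.7 kg (women), 3 MBq/kg dosing, WBC and
hemoglobin within their normal ranges, and smoking prevalence 30%/12%.

Known mismatches, accepted deliberately:

* A single global mediastinal level cannot reproduce both a small %Higher
  volume and a broad spread of Th11 scores; the defaults favor a plausible
  %Higher volume, so nearly all phantom subjects score 2. Score-group
  ANOVA is therefore exercised on simulated grouped data in the tests, not
  on the end-to-end cohort.
* Because the phantom has no subject-level uptake variability beyond the
  age model, age–SUL correlations in synthetic cohorts are near −1,
  much stronger than in real cohorts; only the *direction* of such
  effects, not their magnitude, transfers.
* Marrow is homogeneous in mean — no cervical–lumbar gradient, no focal
  islands; there is no attenuation, scatter, motion or misregistration
  model; vertebra counting is by construction (the Th11 label is ground
  truth), not an algorithm.
* Smoothing biases measured SUL\_mean slightly below truth at marrow
  borders (partial-volume effect); tests allow 0.05 for it. SUL\_max on a
  smoothed blocky phantom is much lower than clinical values, which are
  driven by focal hot spots the phantom does not model.

Passing tests on this phantom therefore demonstrate correctness of the
measurement chain and the statistical machinery — not clinical performance
of the classical segmenter on real, artifact-laden CT.

## Problem sizes and determinism

The test suite runs the unit and property checks on a reduced
48 × 48 × 64 grid and keeps the full default 80 × 64 × 96 geometry for the
end-to-end checks: 10 noiseless phantoms for segmentation accuracy, a
500-subject cohort for direction-of-effect recovery, 1000-replicate null
simulations at n = 200 per statistical test, 100-seed interval-coverage
runs at n = 300, and ICC recovery at 500 subjects × 2 repeats. These sizes
were chosen so Monte-Carlo error is small relative to each check's
tolerance. Every stochastic component — cohort, phantom, perturbations —
derives from an explicit integer seed, and identical seeds give
bit-identical volumes and result tables.

## Limitations

The segmenter is a classical threshold-and-morphology stand-in honoring the
interface of learned whole-bone segmenters, not a reimplementation of one;
on real CT it would need metal-artifact handling and femur separation that
the phantom deliberately avoids. NIfTI-1 headers store spacing as 32-bit
floats, so grid metadata round-trips at single precision while voxel data
round-trip losslessly in 64-bit. DICOM ingestion, PET reconstruction and
scanner calibration are out of scope.
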