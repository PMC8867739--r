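# bmpet — bone marrow FDG-PET/CT quantification with digital phantoms

Whole-body FDG-PET/CT is increasingly used to assess the bone marrow in
hematologic conditions (myeloproliferative neoplasms, aplastic anemia,
myelodysplastic syndromes, lymphoma, myeloma), but the *normal* marrow
uptake pattern has to be established before any of these can be graded
against it. `bmpet` implements a semi-automated quantification pipeline for
skeletal marrow glucose metabolism aimed at exactly that baseline problem:
it segments the spine and pelvic marrow cavity from CT, masks the PET
volume with it, converts voxel values to lean-body-mass-normalized uptake,
and reports first-order histogram features together with reference-region
scores — plus a parametric digital phantom and cohort simulator so that
every stage is testable against exact ground truth without any patient
data.

The intended users are imaging scientists and biostatisticians prototyping
marrow quantification methods, and anyone who needs a fully synthetic,
ground-truthed test bed for PET/CT analysis code.

## Method

**Segmentation.** Bone is extracted from CT by Hounsfield thresholding
(default 150 HU), morphologically closed, filled slice-wise into the bone
envelope, and cleaned of small components. The cortical margin is removed
by two one-pixel binary erosions with a 4-connected cross on each axial
slice, leaving the marrow cavity ("BM CT"); the PET volume masked with it
is the "BM PET". The marrow of the most caudal labeled vertebra (Th11) is
isolated separately for reference-region scoring.

**SUL conversion.** Voxel activity concentrations C (Bq/ml) are normalized
by injected dose D (Bq) and lean body mass:

    SUL        = C / D × LBM(g)
    LBM_man    = 9270 × BW / (6680 + 216 × BMI)
    LBM_woman  = 9270 × BW / (8780 + 244 × BMI)

with BW in kg and BMI = BW / height(m)².

**Per-subject readout.** Marrow volume (voxel count × exact voxel volume),
SUL_max, SUL_mean, Shannon entropy of the 64-bin grayscale histogram over
[0, max] (in bits), the percentage of marrow voxels with SUL strictly above
the mediastinal reference mean (%Higher volume), and a Deauville-style
score of the Th11 marrow SUL_mean: 2 = at/below mediastinum, 3 = above
mediastinum and at/below liver, 4 = above liver.

**Reproducibility and cohort statistics.** Intersection over union between
repeated segmentations, the two-way mixed-effects absolute-agreement
single-measurement ICC for repeated SUL_mean readings, and the cohort
battery: pooled/Welch t-tests and Mann–Whitney U between sexes, Pearson and
Spearman correlations, two-stage univariate → multivariate OLS regression,
one-way ANOVA across score groups, and chi-square/Fisher tests with the
expected-count ≥ 5 rule.

**Phantom.** A blocky torso: 12 stacked vertebral cuboids plus two pelvic
blocks, each an in-plane cortical shell around a marrow core, with
mediastinal and liver reference boxes, on a 4.11 × 4.11 × 5 mm grid. True
marrow SUL follows a linear age model with sex-specific intercepts (men >
women, declining with age); within-marrow dispersion declines with age;
reconstruction effects are emulated with Gaussian smoothing (5 mm FWHM) and
signal-dependent Gaussian noise. The matched cohort simulator draws
demographics, blood indices and 3 MBq/kg dosing per sex.

## Worked example

```r
library(bmpet)
meta <- generate_cohort(1, seed = 42)          # one simulated subject (F, 80 y)
ph   <- generate_phantom(meta, phantom_params(seed = 42))
seg  <- segment_subject(ph$ct, ph$pet, ph$truth)
quantify_subject(ph$pet, seg, meta, ph$truth)
```

```
<bm_quant>
  volume        894.44 cm^3 (10590 voxels)
  SUL_max        0.886
  SUL_mean       0.625
  entropy        4.367 bits (64 bins)
  %Higher        0.000 % (mediastinum 0.921)
  Deauville          2 (Th11 0.614, liver 1.268)
```

This 80-year-old simulated woman has a marrow volume of 894 cm³ and a
measured SUL_mean of 0.625 against a true (generator) marrow SUL of 0.650 —
the small deficit is the expected partial-volume effect of the 5 mm
smoothing at marrow borders. No marrow voxel exceeds the mediastinal mean
(%Higher = 0) and the Th11 marrow sits below the mediastinum, giving
score 2, the typical normal pattern at this age.

A whole simulated cohort runs through `run_pipeline()`:

```r
m <- run_pipeline(n = 50, seed = 7, out_dir = "run50", repro_sessions = TRUE)
m$repro$iou   # mean IoU across perturbed re-reads
```

A thin command-line wrapper is installed at
`inst/scripts/run_pipeline.R`.

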