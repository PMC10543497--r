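# mritype

Rules-based tissuetype segmentation and volumetrics for multiparametric
brain MRI, with a longitudinal time-to-progression model — aimed at
quantitative response assessment in high-grade glioma, where manual
contouring is laborious and deep-learning segmenters trained on
preoperative tumors struggle with resection cavities and diffuse
recurrence.

## What it does

Every brain voxel of a co-registered multiparametric stack (T1w, T1wCE,
T2w, FLAIR, optionally an ADC map) is assigned one of nine tissuetypes —
gray matter (GM), white matter (WM), Fluid, blood vessel (BV),
contrast-enhancing tumor (CE), tumor-associated edema (Edema1),
leukoaraiosis-like edema (Edema2), Hemorrhage, or Background — by an
explainable decision tree over *calibrated* intensities:

1. **Enhancement split.** The difference map `D = T1wCE − T1w` is
   Otsu-thresholded (256-bin histogram, maximizing the between-class
   variance `ω₁ω₂(μ₁−μ₂)²`) into enhancing (VOI8) and non-enhancing
   (VOI1) voxels.
2. **VOI8:** FLAIR-bright → CE, FLAIR-dark → BV.
3. **VOI1:** T2w-hypointense → normal brain (VOI2), T2w-hyperintense →
   fluid/pathologic (VOI3).
4. **VOI2:** WM iff FLAIR-darker *and* T1w-brighter than the GM/WM cuts,
   else GM; then voxels with ADC ≤ 550 µm²/s are overridden to
   Hemorrhage.
5. **VOI3:** Fluid iff FLAIR-hypointense *or* ADC ≥ 2130 µm²/s; else
   Hemorrhage iff ADC ≤ 550 µm²/s *or* T1w-hyperintense; the remainder is
   edematous "high FLAIR" tissue, split into Edema2 (slightly
   T1w-brighter, leukoaraiosis-like) vs Edema1.

Around the tree the package provides:

* **Two-point intensity calibration** — an affine map sending the medians
  of two reference tissues (ventricular CSF, normal WM) onto fixed
  targets, making thresholds transferable across scanners; labels are
  provably invariant to affine distortions of the raw intensities.
* **ADC mapping** — closed-form monoexponential inversion of two-b-value
  DWI, `ADC = ln(S₀/S_b)/b`, in µm²/s.
* **Volumetrics** — abnormal-VOI (abVOI) construction inside a loose
  manual contour (BV/CE/Edema1/Edema2/Fluid voxels; BV relabeled CE),
  per-tissuetype volumes in cm³, High FLAIR = Edema1 + Edema2, and
  composition/correlation analyses against reference ET/ED/NCR
  segmentations.
* **TTP modeling** — `TTP = β₀ + β·x` over per-timepoint abVOI volumes
  and days-on-treatment, selected from all non-empty predictor subsets by
  10-fold cross-validated AIC (held-out Gaussian log-likelihood, k = p+2),
  plus binary progression-within-*n*-days accuracy for n = 30/60/90. The
  reference coefficient set `TTP = 205.6 − 0.6·t_C1D1 − 2.5·CE +
  4.8·Fluid` (days; volumes in cm³) is bundled.
* **A digital brain phantom** — schematic anatomy with ground-truth
  labels, synthesized DWI, calibration masks and a manual VOI, making
  every stage testable end-to-end with no external data.

## Worked example

```r
library(mritype)

ph     <- generate_phantom(phantom_spec(seed = 1))   # 96^3, 2 mm voxels
stack  <- phantom_stack(ph)                          # calibrate + fit ADC
labels <- classify(stack)
labels
#> <tissue_labels> 96x96x96  mode full
#> Background         GM         WM      Fluid         BV         CE     Edema1
#>     547264     151120     164070       2200       2488       1976      11364
#>     Edema2 Hemorrhage
#>       4142        112

ab <- build_abvoi(labels, ph$manual_voi)             # BV -> CE inside abVOI
compute_volumes(ab$reclassified, ab$abvoi)
#>   tissue     voxels volume_cm3 scope
#> 1 GM              0       0    scoped
#> ...
#> 5 CE           2096      16.8  scoped
#> 6 Edema1      11364      90.9  scoped
#> 7 Edema2       1016       8.13 scoped
#> 9 HighFLAIR   12380      99.0  scoped
```

The abVOI CE volume (16.8 cm³) includes 120 reclassified vessel voxels;
High FLAIR is exactly Edema1 + Edema2. On the longitudinal side:

```r
cohort <- generate_cohort(n_patients = 20, scans_per_patient = 10,
                          noise_sigma_days = 10, seed = 1)
model <- select_model(cohort, seed = 1)
model
#> <ttp_model> TTP = 209.7 -0.6096*t_C1D1 -2.623*ce_cm3 +4.757*fluid_cm3 (days)
#>   mean CV AIC 159.87 over 200 records (seed 1)

predict_ttp(reference_ttp_model(),
            tibble::tibble(t_C1D1 = 0, ce_cm3 = 0, fluid_cm3 = 0))
#> [1] 205.6

run_longitudinal(cohort, seed = 1)$accuracy
#>   cohort horizon_days accuracy
#> 1 all              30     0.99
#> 2 all              60     0.96
#> 3 all              90     0.96
```

Subset selection recovers exactly the three generating predictors from
the six candidates (Edema1, Edema2 and their sum are rejected), with
coefficients within sampling error of the generating values. A
prediction at treatment start with no enhancing tumor and no intratumoral
fluid is the model intercept, 205.6 days.

A command-line front end for shell use lives at `inst/cli/mritype.R`
(subcommands `phantom`, `adc`, `segment`, `fit-ttp`, `predict-ttp`,
`horizon-accuracy`).

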