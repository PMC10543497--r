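---
title: "Methods: rules-based tissuetype segmentation and TTP modeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rules-based tissuetype segmentation and TTP modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mritype)
```

## The problem and the model

Quantitative response assessment in high-grade glioma needs volumes of
distinct intratumoral tissue compartments — enhancing tumor, edema,
fluid, hemorrhage — from standard-of-care multiparametric MRI, on every
scan date, without manual contouring of each compartment. `mritype`
implements a purely voxelwise decision tree over calibrated intensities.
Because every rule is a threshold on a calibrated scale or on a physical
ADC value, the classifier is explainable, deterministic, unaffected by
resection cavities, and applicable unchanged to preoperative and
recurrent disease.

The tree assumes:

* the five volumes are co-registered and resampled to a single grid
  (registration is upstream; `assemble_stack()` *verifies* grid identity
  to an absolute tolerance of `1e-3` on spacing and affine entries and
  refuses mismatches rather than resampling silently);
* structural intensities have been mapped to the package's calibrated
  scale (below), so that fixed cuts are meaningful across scans and
  scanners;
* ADC, when present, is in µm²/s (physical units, never calibrated).

## Intensity calibration

MRI structural intensities are in arbitrary scanner units. `calibrate()`
fits the affine map `a·x + b` sending the observed medians of two
reference tissues — ventricular CSF and normal-appearing white matter —
onto fixed targets, and applies it voxelwise. Two properties are load
bearing and tested end to end:

* **Affine invariance.** For any raw distortion `x ↦ αx + β` (α > 0) the
  calibrated output, and hence every downstream label, is unchanged.
* **Idempotence.** Calibrating an already-calibrated volume with the same
  references is the identity.

The median (default) is preferred over the mean for robustness to stray
voxels in hand-drawn reference masks. Degenerate calibrations (equal
reference medians) and empty masks are hard errors. ADC volumes are
tagged `"physical-units"` and refuse calibration.

The per-modality target values define the calibrated scale and are
configuration, not code. The package's canonical scale (the defaults in
`canonical_intensities()`, e.g. WM = 500 and CSF = 150 on T1w) was chosen
so that the default decision cuts sit between the relevant tissue means
with comfortable margins; a user reproducing a particular scanner setup
should supply their own targets and cuts together.

## Decision thresholds

All cuts live in `threshold_config()`, are serialized into the
provenance of every label map, and default to:

| parameter | default | units | role |
|---|---|---|---|
| `adc_hemorrhage_max` | 550 | µm²/s | at/below: hemorrhage (literature value) |
| `adc_fluid_min` | 2130 | µm²/s | at/above: free fluid (literature value) |
| `t2w_hyper_cut` | 250 | calibrated | VOI2/VOI3 split |
| `flair_bv_cut` | 300 | calibrated | CE (at/above) vs BV within VOI8 |
| `flair_fluid_cut` | 150 | calibrated | FLAIR-suppressed fluid in VOI3 |
| `flair_gmwm_cut`, `t1w_gmwm_cut` | 250, 450 | calibrated | WM iff FLAIR below AND T1w above |
| `t1w_hemorrhage_cut` | 600 | calibrated | T1w-bright hemorrhage |
| `t1w_edema_cut` | 345 | calibrated | Edema2 (above) vs Edema1 |

Conventions, fixed once and documented rather than configurable:

* The two ADC cutoffs are **inclusive** (≤ 550, ≥ 2130); all
  calibrated-intensity cuts are strict.
* In VOI3 the **fluid test precedes the hemorrhage test**: a FLAIR-dark,
  T1w-bright voxel is Fluid.
* The VOI2 hemorrhage rule is applied as an **override after** GM/WM
  assignment.
* GM/WM discrimination requires **both** FLAIR and T1w conditions (AND);
  either-condition variants misclassify GM with atypical single-sequence
  values.
* Within the enhancing set, **FLAIR-bright → CE** and FLAIR-dark → BV
  (tumor is FLAIR-hyperintense, flowing blood is FLAIR-suppressed). The
  reverse convention is not supported.
* Otsu is applied once to the pooled in-brain 3-D sample of the
  difference map, not per slice: per-slice thresholds would make labels
  depend on slice geometry and destabilize thin-slice acquisitions.

## Otsu thresholding

`otsu_threshold()` is the classical histogram algorithm: 256 equal-width
bins over the sample range; the cut point maximizing the between-class
variance is returned. When several boundaries tie (two well-separated
point masses make every cut in the gap optimal) the **mean of the tied
boundaries** is returned, making the function deterministic and centered.
Constant input is an error ("no contrast to threshold"). The test suite
checks the implementation against an independent exhaustive search over
all cut points on every tested sample.

Otsu's known failure mode — extreme class imbalance, where splitting the
bulk of a unimodal noise distribution can outscore the true gap — is
real and reproducible: it appears in this package's phantom when the
enhancing fraction of the brain drops well below one percent at
appreciable noise. In clinical difference maps the enhancing fraction
(tumor rim plus vasculature) is above this regime, and the phantom's
geometry mirrors that.

## ADC mapping

With exactly two b-values (0 and 1000 s/mm² clinically) the
monoexponential model inverts in closed form; no least-squares machinery
is warranted. Signals are floored at `1e-6·max(S₀)` before the log;
voxels whose `S₀` does not exceed the floor (air, EPI edge artifacts)
get ADC 0 and an `adc_unavailable` flag. Flagged voxels **fall through
to the intensity-only predicates** individually during classification —
the tree degrades gracefully per voxel rather than per scan.

## Volumetrics

The abnormal VOI is the intersection of a loose manual contour with the
voxels labeled BV, CE, Edema1, Edema2 or Fluid; BV inside it is
relabeled CE (enhancing voxels inside the tumor contour are
overwhelmingly tumor). Hemorrhage inside the contour is counted and
reported but deliberately excluded from the abVOI. Conservation laws are
asserted on every phantom run: relabeling changes no total labeled
volume, CE volume is non-decreasing, High FLAIR = Edema1 + Edema2
exactly, composition percentages sum to 100.

## TTP model selection

Records are patient-timepoints: days on treatment (`t_C1D1`), abVOI
volumes in cm³, and observed time to progression (negative for
post-progression timepoints, `NA` for non-progressors, who are excluded
from fitting). Candidate models are **all 2⁶ − 1 non-empty subsets** of
{t_C1D1, CE, Fluid, Edema1, Edema2, High FLAIR} — no interactions or
transforms. High FLAIR equals Edema1 + Edema2, so subsets containing all
three are rank-deficient; they are detected by QR rank and skipped.

Each subset is scored by 10-fold cross-validated AIC: a seeded random
permutation assigns records to 10 nearly equal segments; an OLS fit on
each 9/10 training split is scored by
`AIC = −2·ℓ_holdout + 2(p + 2)`, where `ℓ_holdout` is the held-out
segment's Gaussian log-likelihood under the training coefficients and
the training MLE variance, and `p + 2` counts slopes, intercept and σ.
Evaluating the likelihood on the held-out segment is the reading that
uses both the fold structure and the AIC penalty; the in-sample
alternative is available as `aic_on = "train"`. Training variances are
floored at `1e-12` so that noiseless data (RSS = 0) remain comparable:
all perfectly fitting subsets then tie in likelihood and the `2(p+2)`
penalty selects the smallest, which is the correct identification.
Ties in mean CV AIC go to the smaller subset, then lexicographic order.
The winning subset is refit on all records by `lm()`; `tidy()` and
`glance()` expose the refit.

Horizon accuracy binarizes true and predicted TTP at a horizon *n*
(≤ *n* → 1) and reports the agreement fraction — evaluated at n = 30,
60, 90 days by `run_longitudinal()`.

## The phantom: what it emulates, what it does not

`generate_phantom()` builds schematic anatomy — a brain ellipsoid with a
GM shell and WM interior, two CSF ventricles, periventricular Edema2
patches, a lesion (fluid core, CE rim, Edema1 shell, hemorrhagic focus,
all mutually disjoint by construction), and a vessel tree sized so that
the enhancing fraction of brain (~1.3%) is in the clinically realistic
range that keeps the Otsu split well-posed. DWI signals are synthesized
from the true ADC field through the forward model, so `fit_adc()` is
exercised end to end; calibration masks are exported from ground-truth
WM and ventricular fluid; reference ET/ED/NCR masks equal the rim,
shell and core. Every intensity ordering the tree relies on is validated
at construction against the active threshold configuration, and
violations are reported by name.

The central oracle of the repository: at zero noise,
`classify(phantom_stack(...))` reproduces the ground-truth labels at
every voxel. The noisy condition adds i.i.d. Gaussian noise at σ = 5% of
the per-modality inter-tissue contrast span; for ADC the span is taken
over parenchymal tissues (excluding free fluid), because the free-water
endpoint would imply σ ≈ 130 µm²/s — several times the noise of clinical
ADC maps — while the chosen definition gives σ = 45 µm²/s, consistent
with diffusion imaging practice. Under that condition every class holds
Dice ≥ 0.90 at 96³.

What the phantom does **not** emulate — and what passing tests therefore
do not establish about real data: partial-volume mixing at tissue
interfaces, Rician noise statistics, bias fields, misregistration
between sequences, EPI distortion of DWI, and anatomically realistic
shapes. The classifier's behavior under those effects must be assessed
on real images; the paper-trail provenance (thresholds, Otsu cut, seeds)
written beside every output is designed to support exactly that kind of
audit.

Longitudinal cohorts are generated with monotone visit grids (4–6 week
intervals), smoothly varying volumes (baseline + trend + slow
sinusoid), and TTP = reference model + Gaussian noise (σ = 10 days
default). They emulate the smooth per-patient volume dynamics seen in
serial imaging, not treatment-effect structure or informative missingness.

## Problem sizes and numerical tolerances

The shipped tests run the phantom at 40³–48³ voxels for unit checks and
96³ (2 mm isotropic, ~340k brain voxels) for the end-to-end oracle and
noise-robustness checks; cohorts use n = 200 records (20 patients × 10
scans) for parameter recovery, with an n = 2000 contrast for consistency.
These sizes give stable statistics while keeping a full suite run in
seconds. Grid compatibility uses an absolute tolerance of 1e-3;
correlation and composition identities are asserted to 1e-9; closed-form
recoveries (ADC, noiseless OLS) to 1e-8 or tighter.

## Known limitations

* Thresholds are configuration with phantom-consistent defaults, not
  learned; reproducing any particular published intensity scale requires
  the corresponding reference targets and cuts.
* The two-point affine calibration assumes the two reference tissues
  bracket a linear intensity response; strong bias fields violate this.
* Otsu's enhancement split assumes a nontrivial enhancing fraction; a
  scan with essentially no enhancement yields an unstable split (the
  degenerate all-equal case is an explicit error).
* The TTP model is ordinary pooled least squares over timepoints;
  repeated measures within patients are not modeled (no mixed effects),
  matching its proof-of-concept role.
* No survival machinery (censoring, Cox models): non-progressors are
  simply excluded from fitting.
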