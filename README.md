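# tilquant

Quantification of tumor-infiltrating lymphocytes (TILs) in H&E-stained
histology images, from stain-space preprocessing to patient-level survival
stratification.

## The problem

TIL density in standard hematoxylin & eosin sections is prognostic in many
cancers, but manual counting is slow and irreproducible, and
immunohistochemistry adds cost. Computational pipelines detect and classify
nuclei in whole-slide images and aggregate the inflammatory-cell counts into
a per-patient biomarker. `tilquant` provides everything around the detector
— which stays pluggable — for researchers building or validating such
pipelines:

* **Stain tools**: color deconvolution between RGB and HED optical-density
  space (Ruifrok–Johnston vectors by default) and two augmentation policies
  — the photometric/affine set (flip, rotation, scaling, noise, blurs,
  brightness/saturation/contrast) and a linear HED policy that perturbs each
  stain channel as `alpha * OD + beta` with per-channel coefficients drawn
  uniformly from configurable ranges.
* **Patch pipeline**: HSV-threshold tissue detection, physical-unit patch
  grids (e.g. 1000 µm patches at a stated µm/px resolution), context
  sub-patch tiling with mirror padding, and pixel-exact output stitching.
* **Detection contract**: cell records (instance id, centroid, class, area)
  as CSV/GeoJSON, a 4-connected instance-map representation, class-scheme
  harmonization onto {cancer, inflammatory, other}, and a deterministic
  rule-based baseline detector so the pipeline runs with no trained model.
* **Evaluation**: optimal (Hungarian) centroid matching within a physical
  radius, and integrated detection/classification metrics per class *t*:

  ```
  accuracy = (TP + TN) / (TP + TN + FP + FN)
  precision = TP / (TP + FP)
  recall    = TP / (TP + FN)
  F1        = TP / (TP + 0.5 (FP + FN))
  ```

  where a matched pair counts by its ground-truth and predicted classes, an
  unmatched prediction is a false detection, and an undetected ground-truth
  cell of class *t* is a false negative. Counts are micro-averaged across
  patches.
* **Cohort analysis**: per-patient median TIL count, dichotomization at the
  cohort median (strictly-above = high), Kaplan–Meier curves, the log-rank
  test, the Cox hazard ratio (low group as reference, so protective TILs
  give HR < 1) and a significance sweep over all distinct cutoffs.
* **Synthetic generators**: seeded H&E-like patches with exact ground truth
  (nuclei rendered through the stain model) and survival cohorts with a
  planted hazard ratio, so everything is testable offline.

## Worked example

```r
library(tilquant)

# simulate a 256 px H&E-like patch with exact ground truth
gen <- generatePatch(patchSpec(sizePx = 256, seed = 7))
table(gen$records$class)
#>       cancer inflammatory        other
#>            6           12            4

# run the baseline detector and score it against the truth
det <- detectCellsBaseline(gen$patch)
ev  <- evaluateDataset(list(p1 = det$records), list(p1 = gen$records),
                       radiusPx = radiusPxFromUm(3, 0.25))
ev$perClass$inflammatory[c("precision", "recall", "f1")]
#> $precision [1] 1    $recall [1] 1    $f1 [1] 1

# simulate an 87-patient cohort with a planted hazard ratio of 0.3 and
# run the full stratification
co  <- generateCohort(cohortSpec(seed = 7))
res <- analyzeCohort(co)
res
#> CohortResult: 87 patients, cutoff 16 (45 low / 42 high)
#>   log-rank: chi-square 10.232, p = 0.00138
#>   hazard ratio (high vs low): 0.448 (95% CI 0.271-0.741)
#>   sweep: 34 cutoffs, min p = 1.381e-06
```

On this simulated patch the baseline detector recovers every nucleus with
the right class, so all metrics are 1; on the simulated cohort, patients
with above-median TIL counts show markedly better disease-specific survival
(HR 0.448 here — a median-split estimate of the planted protective effect),
and the cut-off sweep shows the significance across every possible
dichotomy.

A command-line wrapper covering simulation, augmentation, tiling, detection,
evaluation and cohort analysis ships at
`system.file("cli/tilquant.R", package = "tilquant")`; YAML profiles for
the augmentation policies and cohort simulation live in
`inst/extdata/`.

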