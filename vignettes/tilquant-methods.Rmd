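---
title: "Methods: TIL quantification, detector evaluation and survival stratification"
author: "tilquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TIL quantification, detector evaluation and survival stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tilquant)
```

# Overview

Tumor-infiltrating lymphocytes (TILs) carry prognostic information in many
solid tumors, including non-small cell lung cancer. `tilquant` implements
the computational scaffolding needed to turn per-cell detections in
H&E-stained whole-slide images into a patient-level prognostic biomarker,
while remaining agnostic about the detector itself: any model that emits
per-cell records (instance id, centroid, class, area) can be evaluated and
fed into the survival analysis. The package covers five stages:

1. **Stain tools** — color deconvolution between RGB and HED
   (hematoxylin/eosin/DAB) optical-density space, and two training-time
   augmentation policies.
2. **Patch pipeline** — tissue detection, physical-unit patch grids,
   context sub-patch tiling with mirror padding, and output stitching.
3. **Detection** — the pluggable detector contract plus a rule-based
   baseline detector so the downstream stages run with no trained model.
4. **Evaluation** — integrated detection/classification metrics over
   optimally matched cell instances.
5. **Cohort analysis** — per-patient median TIL counts, median
   dichotomization, Kaplan–Meier / log-rank / Cox stratification and a
   cut-off significance sweep.

A sixth component, the synthetic-data generators, produces H&E-like patches
with exact ground truth and survival cohorts with planted hazard ratios, so
every stage is testable offline.

# Stain model and augmentation

## Color deconvolution

Stains absorb light multiplicatively, so they add linearly in optical
density (OD). For transmitted intensity $I \in [0, 255]$ we use

$$\mathrm{OD} = -\log_{10}\!\left(\frac{I + \varepsilon}{I_{\max} + \varepsilon}\right),
\qquad \varepsilon = 1,\; I_{\max} = 255 .$$

The $\varepsilon$ offset avoids $\log 0$ at $I = 0$; placing it in both
numerator and denominator makes pure white map to exactly zero OD and makes
the transform exactly invertible on the 8-bit lattice, so the
RGB→HED→RGB round trip is the identity up to quantization (the test suite
asserts a maximum error of 2/255; in practice it is 0). The per-pixel RGB
OD vector is projected through the inverse of a stain matrix whose rows are
the unit-norm absorption spectra of hematoxylin, eosin and DAB. The default
matrix is the conventional Ruifrok–Johnston H&E-DAB set
(`heStainMatrix()`); scanners with calibrated stain vectors can supply
their own `StainMatrix`.

## Linear HED augmentation

`augmentHed()` perturbs each stain channel $c \in \{H, E, D\}$ linearly,
$\mathrm{OD}_c' = \alpha_c\,\mathrm{OD}_c + \beta_c$, and reconverts to
RGB. Coefficients are drawn independently and uniformly per channel from
configurable intervals, with defaults $\alpha_c \in [0.95, 1.05]$ and
$\beta_c \in [-0.05, 0.05]$ OD. Uniform sampling and these interval widths
are package decisions — the policy family only prescribes "a predefined
range" — and both are exposed as arguments and in the YAML profile rather
than hard-coded. Coefficients are sampled once per patch, not per
sub-patch, so the stain appearance stays coherent within a patch.

## Base policy

`augmentBase()` applies the classic photometric/affine set: flip, rotation,
scaling (affine — applied identically to the image and any paired label
map, nearest-neighbor for labels), plus Gaussian noise, Gaussian and median
blur, brightness, saturation and contrast (photometric — image only).
Rotation is restricted to multiples of 90°: those rotations are exact on
the pixel lattice, so they conserve instance labels and areas, which the
invariant tests rely on; arbitrary angles would force interpolation and
border cropping that silently destroy instances. Scaling center-crops or
zero-pads back to the input size, so instances can be clipped at borders —
the one documented exception to label conservation.

# Patch pipeline

Tissue is detected in HSV space: a pixel is tissue when its saturation
exceeds 0.05 and its brightness (value) is below 0.95, i.e. colored and not
glass; the binary mask is cleaned with a median filter (radius 2). These
thresholds are deliberately simple and exposed, since upstream tools vary.

Physical patch sizes convert to pixels with round-half-up
(`patchSizePx(1000, 0.2428)` = 4119 px); the toolkit always trusts the
stated µm/px resolution. Patch grids are non-overlapping, anchored at the
origin, filtered by a minimum tissue fraction (default 0.5) and capped
(default 15 patches) in row-major order — a deterministic stand-in for the
manual tumor-border patch selection used when such datasets are assembled
by pathologists. Automating true tumor-border localization is out of scope.

For inference-style tiling, `extractSubpatches()` partitions a patch into
output windows (defaults follow the common nucleus-segmentation geometries:
270 px input with 80 px output, or 256 px with 164 px) and surrounds each
with real parent-image context where the patch origin makes it available,
mirror-reflected context at image borders (reflection does not repeat the
edge pixel). `stitchOutputs()` verifies the windows tile the extent exactly
— each pixel written once — and offsets per-window instance labels to be
globally unique. Coordinates are 0-based, row-major, with half-open
extents throughout; these conventions are fixed so tests can be bit-exact.

# Baseline detector

The baseline detector exists so the evaluation and cohort stages can be
exercised end-to-end without a trained model; it is a transparent
morphology heuristic, not a learned model, and no claim is made that it
matches deep-learning accuracy on real tissue. Pipeline: hematoxylin OD via
color deconvolution, threshold at 0.3 OD, hole filling, 4-connected
components, minimum-area filter (30 px² at 0.25 µm/px), then per-instance
classification:

* **inflammatory** — area < 120 px² (at 0.25 µm/px; thresholds rescale with
  resolution), eccentricity < 0.8 and mean hematoxylin OD > 0.4: small,
  round, strongly stained;
* **cancer** — area ≥ 120 px²;
* **other** — everything else (e.g. elongated stromal nuclei).

4-connectivity is fixed by contract so instance counts are reproducible.
External detectors enter through the cell-record CSV/GeoJSON contract;
`classScheme()` maps dataset vocabularies (PanNuke, CoNSeP, MoNuSAC) onto
the canonical classes, merging normal-epithelial and neoplastic cells into
"cancer" because those vocabularies do not separate them.

# Evaluation

## Matching

Whether a cell was "detected" is adjudicated by centroid distance: a
predicted and a ground-truth cell may be paired when their centroids are
within a radius (default 3 µm, ≈ 12 px at 0.25 µm/px). Among admissible
pairs the package computes the optimal one-to-one assignment — maximum
cardinality, then minimum total distance — with a Hungarian solver written
for this package (`solveAssignment()`), rather than greedy matching, so the
result does not depend on record order; the tests verify optimality against
exhaustive permutation enumeration. Mask-overlap matching is a plausible
alternative adjudication; centroid-radius is the convention of the public
nucleus-classification datasets and is the documented assumption here.

## Integrated metrics

For a target class $t$, matched pairs and unmatched cells yield
$TP_t, FP_t, FN_t, TN_t$: a matched pair counts by its (ground-truth,
predicted) classes; an unmatched prediction is a false detection counting
toward $FP_t$ (classified $t$) or $TN_t$ (classified other than $t$); an
undetected ground-truth cell of class $t$ counts toward $FN_t$. Then

$$\mathrm{accuracy} = \frac{TP + TN}{TP + TN + FP + FN},\quad
\mathrm{precision} = \frac{TP}{TP + FP},\quad
\mathrm{recall} = \frac{TP}{TP + FN},\quad
F_1 = \frac{TP}{TP + \tfrac{1}{2}(FP + FN)} .$$

Zero denominators yield `NA`, never an exception, and `NA` is reported as
such rather than coerced to 0. Counts are summed over patches before the
equations are applied (micro-averaging); per-patch reports are also
emitted. Micro-averaging is a package decision — single per-class numbers
over a test set can also be macro-averaged — and is stated here because the
two can differ materially on unbalanced patches. `f1FromEstimates()`
supports the manual-validation workflow in which observers estimate
precision and recall on a 10% grid and the harmonic mean is computed from
those estimates.

# Cohort analysis

Each patient's TIL burden is the **median** of their per-patch inflammatory
cell counts (mean of middle two for an even patch count). Patients are
dichotomized at the cohort median of these medians: **high** means strictly
above the cutoff, so ties at the cutoff go to "low" — the reading of
"above-median" grouping; the rule is exposed as an argument because the
opposite convention is also defensible. Groups are compared with the
Kaplan–Meier estimator, the two-group log-rank test and a Cox
proportional-hazards model (delegated to the `survival` package), with the
low-TIL group as reference so protective TILs give HR < 1.

`cutoffSweep()` realizes "all possible dichotomized cut-offs" as the
midpoints between consecutive distinct summary values — every distinct
dichotomy — and reports the raw log-rank p-value at each. No
multiple-testing correction is applied, matching how such sweeps are
conventionally displayed; the raw minimum p-value over ~n cutoffs is
optimistically biased and must not be read as a confirmatory test. Cutoffs
producing a group smaller than 5 are flagged, not dropped. Whether such a
sweep should use log-rank or Cox Wald p-values is ambiguous in practice;
log-rank is used here.

# Synthetic data: what it does and does not emulate

`generatePatch()` places non-overlapping elliptical nuclei by bounded
rejection sampling (10⁴ attempts per nucleus; failure is an error, never a
silent undercount) and renders them **through the stain model**: nuclei
carry hematoxylin plus eosin OD, background only eosin, then Gaussian pixel
noise (sd 2 on the 0–255 scale). Rendering through `hedToRgb()` rather than
painting RGB directly means the baseline detector's hematoxylin
thresholding is principled, and couples the stain, detection and evaluation
modules realistically. Class geometry defaults: inflammatory nuclei small
(major semi-axis 3.5–5 px at 0.25 µm/px), round (axis ratio ≥ 0.75) and
dark (H-OD 0.85–1.0); cancer nuclei large (7.5–10 px); "other" nuclei
elongated (axis ratio 0.3–0.42), emulating stromal cells.

What it does **not** emulate: nuclear texture and chromatin patterns,
touching/overlapping nuclei, stain variation across a slide, tissue
architecture, compression artifacts. Passing tests on these fixtures
therefore demonstrate the correctness of the pipeline's bookkeeping,
geometry and statistics — not that the baseline detector (or any detector)
performs well on real tissue.

`corruptPredictions()` derives predictions from ground truth with known
drop/relabel/jitter/spurious structure and returns the implied confusion
counts in closed form; the tests assert integer equality between this
bookkeeping and the evaluator across 100 seeded scenarios. The equality is
guaranteed when ground-truth centroids are separated by more than the
matching radius plus the jitter and spurious cells stay farther than the
radius from all ground truth, which the generator's separation parameters
enforce.

`generateCohort()` emulates the validation-cohort shape: 87 patients,
patches per patient with median 15 and range 3–16 (a categorical
distribution with mass 0.55 at 15, 0.12 at 16, remainder spread over
3–14 — the published cohort reports only the median and range, so the shape
in between is a package choice), negative-binomial per-patch TIL counts
(means 6 low / 25 high, dispersion 3; overdispersion is typical of cell
counts), exponential survival with hazard $\lambda_0\,h^{[\text{high}]}$
($\lambda_0 = 0.012$/month, i.e. median survival ≈ 58 months in the low
group; planted $h = 0.3$ by default, the magnitude reported for TIL effects
in this setting), and uniform censoring on $(0, u)$ with $u$ solved by
`uniroot` so the expected censored fraction hits the target (default 0.3).

# Numerical choices and problem sizes

* Round-half-up for physical-to-pixel conversion; 0-based half-open
  geometry everywhere.
* Assignment penalties: forbidden pairs cost $r(N+1)$ where $r$ is the
  radius and $N$ the padded problem size, which exceeds any feasible total
  distance, so the solver maximizes matches before minimizing distance.
* `survival` handles ties by its default Efron method in the Cox fit;
  the log-rank test inherits `survdiff`'s floating-point tie tolerance, so
  time-unit invariance holds for reasonable rescalings but not for
  transforms spanning many orders of magnitude.
* Degenerate inputs: empty prediction sets, all-censored cohorts and
  all-identical summaries are defined behaviors (empty matchings, flat KM
  curves, a degenerate-grouping warning) rather than errors.
* Test and acceptance problem sizes are chosen for sub-minute runtimes on
  one CPU: 160–256 px patches with 11–21 nuclei, 100 corruption scenarios,
  200 matching instances of ≤ 6 cells, and 100 replicates of 200-patient
  cohorts per planted hazard ratio. These sizes give the recovery checks
  (median HR within ±25%, CI coverage ≥ 90%) comfortable statistical
  margins at the planted effect sizes.

# Known limitations

* The baseline detector is a size/shape/stain heuristic; on real H&E it
  will undersegment touching nuclei and misclassify atypical morphologies.
* Tumor-border patch selection is approximated by a tissue-fraction grid;
  no tumor localization is attempted.
* Stain normalization to a reference slide (Macenko/Vahadane) and
  GAN-based augmentation are out of scope.
* Proprietary WSI formats are not read directly; convert to TIFF/PNG
  first.
* The cut-off sweep reports raw p-values by design; treat its minimum as
  exploratory.
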