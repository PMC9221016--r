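Package: tilquant
Title: Quantification of Tumor-Infiltrating Lymphocytes in H&E Histology
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A model-agnostic toolkit for quantifying tumor-infiltrating
    lymphocytes (TILs) in hematoxylin and eosin stained histology images.
    Provides color deconvolution between RGB and HED stain space with linear
    stain-space and photometric/affine augmentation policies, tissue detection
    and physical-unit patch tiling with mirror padding and output stitching,
    a pluggable cell-detector contract with a rule-based baseline detector,
    integrated detection/classification metrics over Hungarian-matched cell
    instances, per-patient TIL aggregation with median dichotomization,
    Kaplan-Meier / log-rank / Cox proportional-hazards survival stratification
    and a cut-off significance sweep, plus seeded synthetic generators for
    H&E-like patches with exact ground truth and survival cohorts with
    planted hazard ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    EBImage,
    survival,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse,
    tiff
Config/testthat/edition: 3
biocViews: CellBiology, Classification, Survival, Software
RoxygenNote: 7.3.3
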