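Package: dosepaint
Title: Voxel-Level Dose Painting Analysis for Radiotherapy Planning Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for voxel-level dose-painting-by-numbers analysis in
    radiotherapy: mapping tumour-cellularity maps to heterogeneous dose
    prescriptions with a safety-margin floor, inverse prescription maps for
    treatment planning systems, per-voxel plan conformity scoring (quality
    factor), dose-volume histogram metrics and generalized equivalent uniform
    dose, machine-checkable clinical-goal evaluation, and Poissonian
    linear-quadratic tumour control probability. Includes a synthetic phantom
    generator (nested GTV/CTV geometry, spatially correlated lognormal
    cellularity, perturbed plan doses) so the full pipeline runs without
    patient data, plus paired Wilcoxon signed-rank comparisons with
    Holm-Sidak correction for cohort-level plan comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
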