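Package: lungvent
Title: Ventilation Mapping and Cross-Modality Comparison for Functional Lung MRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for quantitative pulmonary ventilation imaging. Computes
    phase-resolved ventilation maps (regional ventilation RVent and the
    flow-volume-loop cross-correlation metric FVL-CM) from free-breathing
    dynamic proton lung MRI, quantifies breath-hold hyperpolarized-gas
    ventilation images (thoracic-cavity region growing, bias-field
    correction, linear binning), thresholds both into ventilation defect
    maps, and compares them regionally (slab matching, coregistration,
    spatial overlap, Sorensen-Dice) and globally (Spearman correlation,
    Bland-Altman, nonparametric cohort tests). Includes a synthetic 4D
    breathing-lung phantom with known ground truth so the full pipeline is
    testable end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
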