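Package: csfpulse
Title: Craniospinal CSF and Cerebral Blood Flow Dynamics from Cine
    Phase-Contrast MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantification of pulsatile cerebrospinal-fluid (CSF) and
    cerebral blood flow from cardiac-gated phase-contrast MRI velocity
    series: semi-automatic segmentation of pulsatile regions, 32-phase
    volumetric flow curves, stroke volumes, cerebral arterial and venous
    flows, the venous drainage repartition (alpha) factor, the corrected
    venous and arteriovenous flow curves and the intracranial volume
    change over the cardiac cycle. Includes a synthetic-data module that
    generates velocity-image series with known ground truth and two-group
    subject cohorts (Chiari malformation with or without a syrinx) with
    prescribed means, dispersions and correlation structure, plus the
    cohort-level statistical layer (Mann-Whitney group comparison,
    Pearson correlation and linear regression, publication-style tables).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
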