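Package: nmsn
Title: Neuromelanin-Sensitive MRI Quantification of the Substantia Nigra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the substantia nigra on neuromelanin-sensitive MRI
    (volume over the three lowest visible slices, TIV-corrected volume,
    signal-to-noise and contrast-to-noise ratios) and carries the derived
    measurements through the longitudinal biomarker analyses used in
    Parkinson's disease progression studies: cross-sectional and mixed-design
    factorial ANOVA, ROC diagnostics, annualized rates of decline, scanner
    effects, Pearson correlations with max-statistic permutation correction,
    Dice/ICC rater reliability, and per-arm sample-size estimation for
    disease-modification trials. Includes a synthetic midbrain-cohort
    generator (phantom images, ROI masks, rater perturbations, and clinical
    tables) so every stage is testable without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    car,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
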