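Package: vilipower
Title: Mechanical Power of Ventilation and PET/CT Lung Inflammation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis pipeline for experimental ventilator-induced lung
    injury studies. Segments ventilator pressure/flow recordings into
    breaths and computes per-breath respiratory mechanics (peak, plateau,
    driving and transpulmonary pressures; equation-of-motion elastance and
    resistance with a volume-dependent term) and mechanical energy/power by
    numerical integration of the pressure-volume curve, with a
    residual-closed elastic/resistive decomposition. Estimates the 18F-FDG
    uptake rate Ki by Patlak graphical analysis, the blood fraction by an
    irreversible two-tissue-compartment fit, and the tissue-normalized
    uptake rate KiS. Summarizes CT lung aeration into
    Hounsfield-unit-defined compartments, derives gas-exchange indices
    from blood-gas panels, and provides paired asymptotic Wilcoxon tests
    and Spearman correlations following SPSS conventions. A synthetic-data
    module generates all inputs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    pracma,
    RNifti,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
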