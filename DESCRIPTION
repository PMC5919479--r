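Package: rvload
Title: Relative Valve Load and Doppler Hemodynamic Indices for Aortic Stenosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives Doppler-echocardiographic hemodynamic indices of aortic
    stenosis severity (stroke volume and stroke volume index, transvalvular
    gradients, aortic valve area by the continuity equation, percent stroke
    work loss, valvuloarterial impedance, and the relative valve load RVL =
    MG/Zva), classifies flow-gradient phenotypes, and evaluates the prognostic
    value of each index for post-TAVR outcomes via ROC curves with
    Youden-index cutoff selection, paired AUC and sensitivity/specificity
    comparisons, contingency tests, Kaplan-Meier estimation and adjusted Cox
    proportional-hazards models. Includes a calibrated synthetic cohort
    generator so the full pipeline is testable without patient data, and
    utilities to reconstruct 2x2 tables from rounded published summaries.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
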