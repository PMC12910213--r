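Package: mipdsim
Title: Model-Informed Precision Dosing Simulation and Bayesian Forecasting
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for model-informed precision dosing (MIPD) of vancomycin
    and amikacin in critically ill children: closed-form population
    pharmacokinetic models for intravenous infusion regimens, maximum a
    posteriori (MAP) Bayesian estimation of individual parameters from sparse
    therapeutic drug monitoring concentrations, exposure-target dose
    optimization (AUC/MIC, Cmax/MIC) under pediatric safety caps, model-fit
    classification, and paired a priori versus a posteriori prediction-error
    evaluation (MAE, MdAE, MdE). A synthetic virtual-patient PICU cohort
    generator makes the whole analysis reproducible without patient data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    graphics,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
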