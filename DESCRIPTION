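Package: vtmech
Title: Electromechanical Simulation of Ventricular Tachyarrhythmia and
    Prediction of Mechanical Performance from Electrical Instability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Desk-scale electromechanical modelling of ventricular
    tachyarrhythmia. Simulates reentrant arrhythmia in two-dimensional
    (and thin-slab) monodomain tissue with a human ventricular ionic
    model, extracts twelve electrical-instability features (action
    potential duration, wavelength, rotor rotation rate, dominant
    frequency statistics, phase-singularity and filament counts),
    couples tissue calcium to a four-state crossbridge model and a
    lumped-parameter circulation to obtain stroke volume and myocardial
    tension variability, and benchmarks support vector regression
    against multilayer perceptron regressors for predicting the
    mechanical outputs from the electrical features. A calibrated
    copula emulator of the feature table supports fast, reproducible
    benchmarking without running tissue simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    e1071,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
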