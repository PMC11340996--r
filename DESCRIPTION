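Package: vepna
Title: Virtual Epileptic Patient Modelling with Sodium-MRI Derived Priors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Personalized whole-brain network modelling of epilepsy built
    around the 2D-reduced Epileptor neural mass model. Quantifies multi-echo
    sodium (23Na) MRI signals by biexponential T2* fitting with phantom
    calibration, derives per-region excitability priors from SEEG seizure
    spectra (multi-band onset detection) or from sodium features via an
    imbalance-aware logistic-regression pipeline, inverts the network model
    by maximum-a-posteriori optimization of a log posterior over SEEG power
    envelopes, and scores epileptogenic-zone-network estimates with
    epileptogenicity values, sensor-sensitivity bootstrapping and
    confusion-matrix metrics. Includes synthetic-data generators for every
    input so the full workflow is exercisable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
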