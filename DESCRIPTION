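Package: nfdcm
Title: Dynamic Causal Modeling of Steady-State Spectra with Neural Field Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generative modeling of steady-state local field potential and EEG
    spectra with a Jansen-Rit neural field model of a single cortical source.
    The package evaluates closed-form spectral transfer functions of a
    three-population (stellate, interneuron, pyramidal) field model with
    exponential lateral-connectivity kernels and distance-proportional
    conduction delays, predicts single-channel auto-spectra as a sum over
    standing-wave modes, estimates cross-spectral data features from raw time
    series by vector autoregression, and inverts the model with a
    Variational-Laplace scheme that yields posterior densities over log-scale
    parameters together with a free-energy approximation to the log model
    evidence. Bayesian model comparison between the field model and its
    neural-mass limit (zero conduction delay) is supported, along with
    synthetic-data experiments for parameter recovery and spectral sensitivity
    analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
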