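Package: channelnoise
Title: Channel Noise and Spontaneous Spiking in Conductance-Based Neuron Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying how stochastic gating of voltage-gated ion
    channels generates membrane voltage noise and spontaneous action potentials
    in single-compartment conductance-based neuron models. Provides discrete
    Markov-chain simulation of channel populations alongside the deterministic
    rate-equation limit, analytic multi-Lorentzian current-noise power spectra
    derived from channel kinetic schemes, quasi-active (linearized) membrane
    impedance, voltage-noise prediction through the generalized Ohm's law,
    spike-triggered average current analysis, and impedance-calibrated
    Ornstein-Uhlenbeck colored-noise surrogates for estimating spontaneous
    firing rates.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
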