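Package: bagmf
Title: Bootstrap-Aggregated Model-Free Analysis of 15N Spin Relaxation
Version: 0.1.0
Authors@R: person("bagmf", "maintainers", email = "bagmf@example.org",
    role = c("aut", "cre"))
Description: Model-free analysis of backbone amide 15N NMR spin relaxation
    data measured at multiple static magnetic fields. Relaxation rate
    constants (R1, R2, steady-state NOE) are transformed into reduced
    spectral density values J(0), J(omegaN) and J(0.87 omegaH); five nested
    extended model-free spectral density models are fitted by weighted
    least squares and compared with the small-sample Akaike information
    criterion (AICc). Instead of committing to a single selected model, the
    package aggregates model selection and parameter estimation over an
    enumerated, block-constrained non-parametric bootstrap ensemble
    (bagging) and reports smoothed parameter estimates with plug-in
    smoothed standard deviations, alongside conventional Monte Carlo and
    fixed-model bootstrap uncertainties. A synthetic-data generator with
    known ground-truth dynamics supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
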