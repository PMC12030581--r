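Package: plgarelease
Title: Fitting In Vitro Drug-Release Curves of PLGA Delivery Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for modelling cumulative in vitro drug-release curves of
    poly(lactic-co-glycolic acid) (PLGA) micro- and nanoparticle delivery
    systems. Fits the Korsmeyer-Peppas power-law and Weibull
    stretched-exponential release models per sample by bounded multi-start
    nonlinear least squares and classifies the release mechanism from the
    fitted exponent or shape parameter. Additionally provides a multilayer
    perceptron regressor trained on pooled time points that predicts release
    percent from six carrier physicochemical features, fourteen molecular
    descriptors of the encapsulated drug, and the time point. Includes an
    offline drug-name-to-SMILES cache with descriptor computation, per-sample
    MSE and R-squared scoring with aggregate comparison tables, a synthetic
    dataset generator with known kinetic ground truth, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    ChemmineR,
    ChemmineOB,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
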