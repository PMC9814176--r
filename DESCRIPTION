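Package: gpdesign
Title: Optimized Training-Set Design for Multi-Trait Multi-Environment
    Genomic Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing selectively-phenotyped training sets for
    genomic prediction in hybrid crops evaluated in multi-environment,
    multi-trait trials. Covers marker quality control and in-silico hybrid
    synthesis, additive and dominance genomic relationship matrices,
    enviromic (environmental-covariate) kernels, Kronecker composite
    kernels over genotype x environment x trait cells, spectral (APY-style)
    training-set sizing, a look-ahead genetic algorithm with tabu list that
    minimizes mean prediction error variance, multi-kernel Bayesian GBLUP
    with additive, dominance, enviromic and interaction terms fitted by
    Gibbs sampling, CV1/CV2 cross-validation, and response-to-selection
    per dollar economics. A synthetic-data generator emulates partial
    diallel hybrid panels so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    lme4,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
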