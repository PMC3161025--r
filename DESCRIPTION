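Package: raschmiss
Title: Rasch Model Validation of Dichotomous Questionnaires under Item
    Non-Response
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying how missing item responses affect the
    psychometric validation of dichotomous patient-reported-outcome
    questionnaires with the Rasch model.  Provides a simulator of
    informative and non-informative item non-response driven by a latent
    response propensity, fourteen single-imputation strategies (personal
    mean score, item mean score, corrected item mean, item-correlation
    substitution, logistic-model, Mokken-rule, Rasch-model and iterative
    Rasch imputation, worst-case, with deterministic and randomized
    variants where applicable) plus available-case and complete-case
    analysis, marginal-maximum-likelihood estimation of the Rasch model on
    incomplete data with Gauss-Hermite quadrature, weighted-likelihood and
    expected-a-posteriori person estimation, the van den Wollenberg Q1
    goodness-of-fit test, the pairwise Loevinger H scalability coefficient,
    the person separation index, and an orchestration layer that runs full
    Monte-Carlo bias studies across missingness conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
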