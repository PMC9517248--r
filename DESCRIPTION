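Package: eqmediate
Title: Causal Mediation Analysis with a Latent-Class Employment Quality Mediator
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for counterfactual causal mediation analysis when the
    mediator is a nominal latent variable, motivated by the study of whether
    a six-class employment-quality (EQ) typology mediates the relationship
    between gender and health among U.S. wage earners.  Implements
    survey-weighted latent class analysis by EM, Vermunt's three-step
    classification-error correction, joint estimation of a multinomial
    mediator model and a logistic outcome model with exposure-mediator
    interaction, g-computation effect decomposition (total, pure direct,
    total indirect, pure indirect, and mediated-interaction effects on the
    probability-difference and odds-ratio scales), and bias-corrected
    bootstrap confidence intervals.  A calibrated synthetic-data generator
    emulating a General Social Survey wage-earner sample, with a brute-force
    Monte-Carlo oracle for the true counterfactual effects, makes every
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    nnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
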