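Package: biasmeta
Title: Bias-Adjusted Bayesian Meta-Analysis of Binary-Outcome Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Bayesian random-effects meta-analysis of binary-outcome
    randomized trials with adjustment for within-trial biases. Trials at
    high or unclear risk of bias for sequence generation, allocation
    concealment or blinding receive an additive bias term on the log odds
    ratio scale, with an informative normal prior on the log ratio-of-odds-
    ratios scale. Priors can be derived from meta-epidemiological evidence
    (a hierarchical model over a collection of meta-analyses), from expert
    elicitation of interquartile ranges or of selected areas of a reference
    distribution, or from a statistical combination of the two. Includes
    generators for synthetic trial collections and elicitation records with
    known ground truth, intraclass-correlation analysis of assessor
    consistency with parametric-bootstrap confidence intervals, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    rjags,
    coda,
    lme4,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
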