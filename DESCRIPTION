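Package: crowdwise
Title: Confidence-Based Group Formation and Majority-Rule Judgment Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying when individual subjective confidence predicts
    the accuracy of majority-rule group judgments in two-alternative
    forced-choice tasks. Provides a seeded latent-trait generator of synthetic
    behavioral datasets (binary correctness plus 0-100 confidence ratings),
    within- and between-question logistic analyses of the confidence-accuracy
    relationship, confidence-ranked member selection with majority,
    confidence-weighted and transmission-chain aggregation rules, train/test
    resampling simulations of group accuracy with test-worse decompositions,
    Cliff's delta effect sizes, and a-priori sample-size planning for one-way
    ANOVA via the noncentral F distribution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
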