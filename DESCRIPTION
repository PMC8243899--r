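Package: eoltraj
Title: Group-Based Trajectory Modelling of End-of-Life Healthcare Expenditures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how medical and long-term-care spending evolves
    over the final five years of life in decedent cohorts built from monthly
    claims data. Builds death-anchored 60-month expenditure panels from
    long-format claims, fits group-based trajectory models (finite mixtures of
    polynomial mean curves on the log-expenditure scale) by an EM algorithm
    with multiple restarts, selects the number of groups and curve orders by
    BIC with a minimum-group-size rule, evaluates classification adequacy
    (average posterior probability, odds of correct classification, bootstrap
    confidence intervals for group proportions), relates trajectory membership
    to patient factors via multinomial logistic regression, cross-tabulates
    trajectories across expenditure categories, and ships a calibrated
    synthetic decedent-cohort generator with latent trajectory groups and
    zero-inflated long-term-care spending so the whole pipeline is testable
    without access to restricted claims databases.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    nnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
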