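Package: vtdisparity
Title: Virtual Twins Subgroup Discovery for Disparities in Treatment Access
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Two-step virtual-twins subgroup analysis for detecting
    covariate-defined subgroups in which a binary group attribute (such as
    race) most increases the probability of a binary adverse outcome (such
    as waiting one day or more to enter opioid-use-disorder treatment).
    Step 1 fits a probability classifier for the outcome given group and
    covariates; Step 2 grows a CART-style regression tree on the per-record
    counterfactual probability difference Z = f(1, X) - f(0, X) to extract
    interpretable subgroup rules, which are then validated on the full data
    with continuity-corrected two-proportion tests under Bonferroni
    multiplicity control. Includes a synthetic episode-table generator with
    planted subgroup effects and a closed-form oracle for the true
    counterfactual difference, a data-preparation layer with Table-1-style
    descriptive comparisons, and a repeated-split classifier comparison
    harness.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ranger,
    glmnet,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
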