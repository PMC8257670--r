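Package: hypomir
Title: Derivation and Validation of Hypoxia-Associated miRNA Expression
    Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for deriving tumour-hypoxia miRNA expression signatures
    from in vitro qPCR screens and bulk expression cohorts, and for
    validating them in randomised-trial survival data. Implements
    delta-delta-Ct differential expression with geometric-mean
    endogenous-control normalisation, Boruta shadow-feature selection
    against an mRNA hypoxia-signature anchor, Spearman/FDR correlation
    filtering into a signed (up minus down) signature score, quantile
    stratification, and Cox proportional-hazards prognosis,
    within-stratum treatment-benefit and treatment-by-hypoxia interaction
    analyses. A synthetic-data module generates qPCR plates, expression
    cohorts and two-arm trials with recorded ground truth so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    survival,
    ranger,
    jsonlite,
    yaml,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
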