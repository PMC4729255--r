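Package: sporotraits
Title: Trait-Based Null Models for Macrofungal Fruit-Body Assemblages
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing reproductive traits (fruit-body size and
    number) of ectomycorrhizal and saprotrophic fungal assemblages along
    resource-availability gradients. Computes unweighted assemblage mean
    traits from long-format fruit-body inventories, scores them against a
    richness-matched regional-pool null and a fixed-fixed independent-swap
    null via standardized effect sizes, summarises stand structure with a
    correlation-matrix PCA, and regresses raw and SES metrics on the
    resulting resource gradient with heteroscedastic random-intercept
    linear mixed models. Includes a synthetic-data generator that emulates
    multi-year fruit-body inventories with configurable trait filtering,
    so the whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    nlme,
    jsonlite
Config/testthat/edition: 3
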