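Package: mutpanel
Title: Mutation-Count Gene Panels for Predicting Immunotherapy Survival
    Benefit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discovers minimal somatic-mutation gene panels that stratify
    survival after immune checkpoint inhibitor therapy in non-small cell
    lung cancer. Genes are ranked by random-forest variable importance and
    pruned by a sequential backward search with an adaptive step schedule
    under 10-fold cross-validation; the resulting panel classifies samples
    into mutant (MT) and wild-type (WT) groups by counting mutated panel
    genes against a threshold. Includes MAF-like mutation table readers
    with the standard variant-level filters, tumor mutational burden,
    rule-based comparator biomarkers (KEAP1-driven co-mutation, DDR),
    Kaplan-Meier / log-rank / Cox / ROC evaluation, and a synthetic cohort
    generator with planted panel signatures for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    pROC,
    ranger,
    stats,
    survival,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
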