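Package: coexmr
Title: Bait-Gene Mutual-Rank Coexpression Meta-Analysis and
    Tissue-Specificity Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Guilt-by-association candidate gene discovery from multiple
    normalized expression experiments. Computes per-experiment mutual
    coexpression ranks (MR, the geometric mean of the two reciprocal
    Pearson-correlation ranks) against a set of bait genes, combines
    ranks across heterogeneous experiments, and selects candidates under
    joint MR thresholds. Also provides a developmental-stage expression
    exclusivity screen (caryopsis/endosperm-restricted expression with a
    defined peak window), condition mean +/- SE profiles, genotype
    contrasts, and a synthetic expression-atlas generator with a planted
    coexpressed module so every stage of the pipeline can be validated
    against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
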