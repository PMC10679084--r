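Package: wbcmr
Title: Two-Sample and Multivariable Mendelian Randomization for GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization from GWAS summary
    statistics, built around the leukocyte-count / rheumatoid-arthritis study
    design: instrument selection (genome-wide significance filter, greedy LD
    clumping, confounder exclusion, palindrome removal, F statistics), allele
    harmonization across exposure and outcome files, inverse-variance-weighted,
    MR-Egger and weighted-median estimators with Cochran's Q, leave-one-out and
    funnel/scatter diagnostics, MR-PRESSO outlier detection, multivariable MR
    with conditional instrument-strength statistics, Bonferroni-corrected
    reporting, and a synthetic GWAS summary-statistics generator with known
    causal truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
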