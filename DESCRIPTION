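Package: mrscreen
Title: Two-Sample Mendelian Randomization Screening for GWAS Summary
    Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for screening many exposure-outcome pairs with
    two-sample Mendelian randomization from GWAS summary statistics:
    instrument selection and linkage-disequilibrium clumping, allele
    harmonization, five causal-effect estimators (Wald ratio,
    inverse-variance weighted, maximum likelihood, MR-Egger, weighted
    median), pleiotropy and heterogeneity diagnostics including a
    recursive MR-PRESSO outlier-pruning loop, Steiger directionality,
    per-taxonomic-level multiple-testing control, bidirectional screens,
    and a synthetic summary-statistics generator with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: jsonlite, stats, utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
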