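Package: prediabgrs
Title: Weighted Genetic Risk Scores for Prediabetes from OGTT Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for testing whether a weighted sum of type-2-diabetes risk
    alleles predicts prediabetic states defined from oral glucose tolerance
    tests (OGTT). Implements ADA-based glycemic classification (NGT, isolated
    IFG, isolated IGT, IFG+IGT), the Matsuda/DeFronzo insulin sensitivity
    index and HOMA indices, simple and log-odds-weighted genetic risk scores
    over a configurable SNP panel, exact Hardy-Weinberg quality control,
    covariate-adjusted logistic models with likelihood-ratio tests and
    stratified (sex, obesity, insulin-sensitivity) analyses, closed-form
    power and sensitivity calculations, and a calibrated synthetic-cohort
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
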