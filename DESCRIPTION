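Package: nat2pgx
Title: Pharmacogenomic Association and Clinical Validity of NAT2
    Acetylator Status for Isoniazid Liver Injury
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Case-control pharmacogenomic analysis pipeline for
    isoniazid-induced liver injury (INH-DILI) built around the NAT2
    acetylator phenotype. Provides a seeded cohort simulator with
    haplotype-based NAT2 genotypes, genotype quality control (call rate,
    exact Hardy-Weinberg test, identity-by-state, heterozygosity, PCA),
    rule-based acetylator phenotype inference and tag-SNP classification,
    candidate-SNP logistic association under additive, dominant and
    recessive genetic models with correlated multiple-testing adjustment
    via multivariate normal probabilities, clinical validity measures
    (Bayes predictive values, population attributable fraction, number
    needed to test, Youden's J), and ROC comparison of clinical versus
    clinical-plus-genetic risk models with DeLong's test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    mvtnorm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
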