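Package: broodmate
Title: Genetic Benefits of Social Mate Choice in Double-Breeding Birds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for testing the good-genes and genetic-compatibility
    hypotheses of social mate choice in facultatively double-breeding passerines
    from codominant microsatellite genotypes. Provides GenePop and long-form CSV
    genotype input, marker quality control (Monte-Carlo exact Hardy-Weinberg tests,
    Chakraborty and Brookfield null-allele estimators, genotypic linkage-disequilibrium
    permutation tests), Ritland moment estimators of pairwise relatedness and
    individual inbreeding, standardized multilocus heterozygosity, year-stratified
    dyadic randomization tests with two-tailed empirical critical values,
    binomial-logit mixed models with all-subsets AICc model selection and Akaike
    weights, and a Mendelian population simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
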