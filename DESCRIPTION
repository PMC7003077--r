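Package: forageGS
Title: Genomic Prediction of Nutritive Traits in Half-Sib Forage Breeding Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-stage genomic selection workflow for half-sib family
    evaluation trials in outcrossing forages such as perennial ryegrass.
    Simulates multi-population polycross panels with genotyping-by-sequencing
    (GBS) allele reads and multi-location row-column trials; performs per-SNP
    quality control (call rate, minor allele frequency, mean depth,
    Hardy-Weinberg disequilibrium) and mean imputation; builds VanRaden and
    depth-adjusted (KGD) genomic relationship matrices from low-coverage GBS
    data; fits multi-component linear mixed models by average-information REML
    to estimate family, family-by-location and design variance components,
    family-mean repeatability and genomic heritability; estimates genotypic and
    phenotypic correlations among traits; and predicts genomic estimated
    breeding values by GBLUP, KGD-GBLUP and BayesC-pi, evaluated by k-fold,
    Monte-Carlo, within-population and marker-density-ladder cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    tools,
    Rcpp,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    withr,
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
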