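Package: famvar
Title: Genetic and Shared-Environment Variance Decomposition in Family Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Partitions the phenotypic variance of quantitative traits measured
    in family-based genotyped cohorts into contributions tagged by a genomic
    relationship matrix (G), a relatedness-thresholded kinship matrix (K), and
    binary shared-environment matrices for nuclear families (F), full siblings
    (S) and couples (C), using average-information restricted maximum
    likelihood with boundary-aware likelihood-ratio tests, backward stepwise
    model selection, and bivariate models for genetic correlations. Includes a
    gene-dropping simulator for multi-generation pedigrees, genotypes and
    phenotypes with known variance structure, genotype quality control with an
    exact Hardy-Weinberg test, multidimensional-scaling ancestry components,
    Likert questionnaire scoring for resilience and coping-style instruments,
    and readers/writers for PLINK bed/bim/fam and GCTA binary GRM files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0), yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
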