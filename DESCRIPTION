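Package: SomaticSexBias
Title: Three-Stage Detection of Sex-Biased Somatic Genomic Features in
    Cancer Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a three-stage statistical framework for detecting
    sex differences in somatic genomic features of tumour cohorts: driver
    mutation frequency, mutation density, chromosome and genome instability,
    gene-level copy number aberrations, clonal structure and mutation
    timing, and mutational signature presence and activity. Stage one
    screens every feature with non-parametric univariate tests under
    analysis-specific Benjamini-Hochberg false discovery rate families;
    stage two adjusts candidates for clinical covariates with logistic
    regression or linear regression on Yeo-Johnson transformed values;
    stage three vets significant findings with down-sampling analyses that
    probe tumour-subtype and sex sample-size imbalance, plus extended
    models incorporating tumour stage and grade. A synthetic-cohort
    generator with configurable planted sex effects makes every stage
    testable without access to controlled genomic data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    car
Config/testthat/edition: 3
biocViews: StatisticalMethod, SomaticMutation, CopyNumberVariation,
    Regression, MultipleComparison
RoxygenNote: 7.3.3
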