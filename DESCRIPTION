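Package: prsScan
Title: Polygenic Risk Score Construction and Symptom-Association Scans
    for Huntington's Disease Cohorts
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Construct clumped, multi-threshold polygenic risk scores (PRS)
    from GWAS summary statistics and dosage genotypes, adjust them for
    population stratification by principal components, and scan them against
    binary psychiatric and cognitive symptom endorsements with two-level
    Bonferroni control, conditional multi-PRS models, and descriptive cohort
    statistics. Includes a synthetic cohort generator (block-LD haplotypes,
    training GWAS, liability-threshold symptoms with a shared latent factor)
    so the full pipeline is testable without access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    BiocGenerics,
    GenomeInfoDb,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Genetics, SNP, GenomeWideAssociation, StatisticalMethod
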