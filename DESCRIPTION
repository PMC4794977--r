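Package: rohtools
Title: Runs of Homozygosity, Genomic Inbreeding and SNP Heritability for
    Case-Control Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects runs of homozygosity (ROH) in case-control SNP
    genotype data with a sliding-window caller, tests SNP-level
    homozygosity against disease status with false discovery rate
    control, pools overlapping ROH into consensus regions and tests
    recurrent regions for case enrichment, computes three SNP-based
    genomic inbreeding coefficients and the ROH-based coefficient
    F_ROH, and estimates the phenotypic variance explained by common
    SNPs via genetic relationship matrices and average-information
    REML with a liability-scale transformation. Includes PLINK binary
    genotype input/output and a synthetic cohort simulator with
    linkage-disequilibrium blocks, controllable inbreeding, planted
    autozygous segments and recessive disease loci so that every stage
    of the pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: SNP, GenomeWideAssociationStudy, Genetics, StatisticalMethod
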