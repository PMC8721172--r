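Package: oodosage
Title: Sex-Chromosome Dosage Analysis of Oocyte Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for comparing XX, XO, and XY mouse
    oocyte transcriptomes from 5' UMI-tagged RNA-seq. Implements tag
    detection and UMI deduplication for modified Smart-seq3 reads, ERCC
    spike-in size-factor normalization with PCA and Spearman-distance
    quality control, per-gene linear models with residual-PCA surrogate
    covariates and empirical-Bayes moderated t-statistics, directional
    differential-expression lists with four-set Venn partitioning into
    sex-chromosome-dosage categories, lognormal X-dosage ratio fitting,
    binned bootstrap X:autosome expression-ratio statistics, Y-linked and
    pseudoautosomal gene expression classification, homolog-sum
    comparison, and qRT-PCR relative quantification. A first-class
    synthetic-data generator emulates the study design (three genotypes in
    biological triplicate, ERCC spike-ins at a 3-6% read fraction,
    Poisson-lognormal counting noise, tagged 5' reads) so that every stage
    is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
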