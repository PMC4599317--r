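Package: meqtlscan
Title: Cis-meQTL Discovery with Covariate and Cell-Composition Adjustment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for mapping cis methylation quantitative trait loci
    (meQTLs) from Illumina 450K-style methylation arrays and candidate SNP
    genotypes. Pairs SNPs with CpG probes within a configurable cis window,
    fits a covariate-adjusted linear model per pair on the M-value scale
    (sex, age, weight category, and a two-principal-component surrogate for
    blood cell-type composition), tests the genotype term with a likelihood
    ratio test, and controls the false discovery rate with Storey q-values.
    Associated CpGs are annotated against gene models, chromatin-state
    segmentations, enhancers, and ChIA-PET long-range interaction anchors,
    with Fisher exact enrichment tests. Includes a synthetic-data generator
    with planted effects and known ground truth so the full pipeline is
    testable without cohort data, plus noncentral-F power calculations for
    replication designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lmtest,
    withr,
    vcfR
Config/testthat/edition: 3
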