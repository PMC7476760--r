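Package: supergeneASE
Title: Allele-Specific Expression and Dosage-Compensation Analysis for
    Social Supergenes
Version: 0.1.0
Authors@R:
    person("supergeneASE", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to study expression evolution of a non-recombining
    supergene from haploid genotypes and heterozygote RNA-seq. Identifies
    SNPs with fixed allelic differences between two haplotype groups,
    summarizes allele-resolved read counts to gene-level SB/Sb expression,
    tests allelic bias with weighted linear mixed models and paired
    negative-binomial GLMs, performs social-form differential expression
    with median-of-ratios normalization, and discriminates degeneration,
    dosage compensation and antagonistic selection through closed-form
    allelic/social proportion curves and quadrant classification. Includes
    a fully parameterized synthetic-data generator with known per-gene
    regimes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    lme4,
    withr,
    jsonlite,
    Biostrings,
    VariantAnnotation,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
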