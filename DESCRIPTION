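Package: plasmacall
Title: Replicate-Aware Low-Frequency Variant Calling for Amplicon ctDNA Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analytical validation of amplicon-based circulating
    tumor DNA (ctDNA) assays. Implements a replicate-aware variant caller for
    low allele-fraction single-nucleotide variants and indels, with per-position
    beta-binomial background error models fitted from control samples and
    maximum-likelihood integration of evidence across technical replicates.
    Includes digital PCR Poisson quantification and dual-binomial limit-of-
    detection statistics, copy-number inference from normalized amplicon read
    depth, cross-sample contamination checks from common SNPs, analytical
    validation statistics (exact binomial confidence intervals, pooled
    sensitivity, per-base specificity, precision, extraction efficiency), and a
    synthetic-data stack emulating sheared reference-standard dilution series
    and spiked full-process plasma controls.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'background-model.R'
    'dpcr.R'
    'panel-io.R'
    'read-processing.R'
    'synthetic-data.R'
    'utils.R'
    'validation-stats.R'
    'variant-calling.R'
    'vcf-io.R'
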