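Package: chromccs
Title: Comparative Chromatin Accessibility Analysis of the Cardiac Conduction System
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for multi-sample ATAC-Seq peak-set comparison
    centred on the cardiac conduction system (sinoatrial node, atrioventricular
    node, ventricular conduction system) against working cardiomyocytes.
    Provides genomic-interval algebra with BED input/output, n-way region
    partitioning and open/closed occupancy classification, position-weight-
    matrix motif scanning with fold-enrichment ranking and motif-based
    transcription-factor to gene network construction, enhancer prioritization
    against active-mark and validated-enhancer catalogs with target-gene
    nomination, block-based coordinate liftover with GWAS-variant landing-
    frequency enrichment statistics, and a deterministic synthetic-data
    generator that plants known structure for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
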