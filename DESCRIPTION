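Package: capkit
Title: Target-Capture Panel Design, Enrichment QC, and Diagnostic SNP
    Analysis for Timber Genomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An analysis toolkit for hybridization-capture genomics of
    tropical timber trees. Ranks transcript models by genomic-read
    coverage per kilobase (RPK) to select putatively low-copy gene
    targets, tiles fixed-length hybridization probes across targets,
    quantifies capture enrichment and cross-taxon transferability
    (on-target yield, per-target depth, reliably enriched target sets,
    organelle-depleted subsampling, Welch t-tests), filters multi-sample
    variant calls and ranks species-diagnostic SNPs by per-site Weir and
    Cockerham F_ST with species treated as populations, and builds
    reference-guided organelle consensus sequences with a minimum-depth
    N-masking rule. Includes synthetic-data generators with planted
    ground truth so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
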