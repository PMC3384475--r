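Package: strainCGH
Title: Array-CGH Gene Content Analysis for Bacterial Strain Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calibrated gene presence/absence calling from two-channel
    comparative genomic hybridization (CGH) microarrays, and downstream
    gene-content analysis for sets of bacterial strains compared against a
    fully sequenced reference. Implements normexp background correction
    with an intensity offset and print-tip loess normalization,
    fold-over-background presence calling with cutoff calibration against
    strains of known gene content (plasmid-cured derivatives), core-genome
    and pairwise shared-gene statistics, region/gene-set occupancy tables,
    complete-linkage clustering of strains with gene-resampling bootstrap
    supports, and pattern-based detection of candidate genomic islands as
    runs of variably present genes. A synthetic-data generator produces
    reference-like genomes, strain gene contents and noisy two-channel
    scans with known ground truth, so the whole pipeline is testable
    without scanner output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    limma,
    ape,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
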