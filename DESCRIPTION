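Package: epiwindow
Title: Window-Based Enrichment Analysis for MeDIP-seq and ChIP-seq
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fixed-width window quantification of immunoprecipitation
    sequencing data (MeDIP-seq, ChIP-seq) with depth normalization and
    matched-input subtraction, percentile-threshold peak calling with a
    2-of-3 consecutive-window rule, mapping of peaks to six genomic
    compartments, strand-aware metagene and element profiles, unique
    assignment of fragments to retrotransposon annotations, bisulfite
    clone and HPLC methylation quantification, and DigiWest 96-fraction
    analytics including a permutation two-factor ANOVA. Ships a
    synthetic-data module that generates every pipeline input with
    planted ground truth so the whole analysis is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
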