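Package: trophreg
Title: Trophectoderm Lineage Regulatory Genomics on Planted-Truth Synthetic Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream computational analyses for studying how a lineage-restricted
    transcription factor (modelled on CDX2 in mouse trophoblast stem cells) partitions
    the early-embryo regulatory landscape. Implements intensity-weighted,
    exponentially distance-decayed TF-to-gene association scores with genome ranking
    and top-N target calling; genomic-interval intersection with a configurable border
    gap, co-occupancy and triple-overlap queries; genome-wide calling of candidate
    lineage-specific silencers (TF binding + DNase hypersensitivity + H3K27me3) with
    nearest-TSS gene assignment; fold-change differential expression and
    sliding-window association profiles over expression-ranked genomes; and
    single-embryo qPCR delta-Ct analysis with genotype classification, hierarchical
    clustering, and a two-axis anchor-gene correlation map. A synthetic-data module
    generates every pipeline input with planted ground truth so all stages are
    testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    ggplot2,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
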