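Package: dapmap
Title: DAP-Chip Tiling-Array Analysis for Response-Regulator Binding Targets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for DNA-affinity-purified chip (DAP-chip)
    experiments that map bacterial two-component response-regulator binding
    targets on tiling microarrays. Implements scaled log2-ratio computation,
    sliding-window peak detection over a descending cutoff schedule anchored
    at the hypothetical maximum ratio, per-peak false-discovery estimation by
    track randomization, mapping of peaks to upstream regions of genes and
    operons with mechanical curation rules, position-weight-matrix scanning
    for binding-site motifs and sigma54 promoters, and qPCR fold-enrichment
    arithmetic. A synthetic-data module generates operon-structured genomes,
    tiling probe designs, planted binding sites and simulated enrichment
    tracks so the whole pipeline can be exercised and benchmarked without
    array downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    methods
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
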