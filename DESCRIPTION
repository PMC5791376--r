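Package: fragsynt
Title: Robustness of Synteny Block Detection to Genome Assembly Fragmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation framework for quantifying how genome assembly
    fragmentation corrupts anchor-based synteny inference. Generates genome
    pairs with known one-to-one orthology and ground-truth synteny blocks
    (emulating gene densities of chromosome-scale nematode assemblies),
    fragments assemblies to controlled N50 by random fixed-size breaking,
    detects synteny blocks by chaining ortholog anchors, and measures the
    resulting synteny-coverage error rate across fragment sizes and
    replicates. Also reproduces two downstream failure modes: rank
    instability of gene-ontology enrichment on synteny-break genes, and
    false collinearity introduced by reference-guided scaffolding of a
    fragmented assembly.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
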