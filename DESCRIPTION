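Package: smmipkit
Title: Single-Molecule Molecular Inversion Probe Panel Screening Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computational core of a targeted gene-panel screening assay
    built on single-molecule molecular inversion probes (smMIPs). Provides
    probe-panel modelling and tiling validation, unique-molecular-barcode
    (UMB) read assignment and deduplication with per-probe coverage
    reports, capture-pool rebalancing recipes, exon-level read-depth copy
    number variant calling with a beta-binomial hidden Markov model, qPCR
    delta-delta-Ct relative quantification for copy-number confirmation,
    and cohort diagnostic-yield and concordance statistics. A synthetic
    cohort simulator generates toy references, constraint-satisfying
    panels, and UMB-tagged reads with injected variants and a truth
    manifest, so the whole pipeline is exercisable end to end without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
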