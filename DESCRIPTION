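Package: g4scape
Title: Genome-Wide Putative G-Quadruplex Scanning, Regulatory-Feature
    Enrichment and Expression-Variability Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scans nucleotide sequences on both strands for putative
    G-quadruplex (pG4) motifs (runs of guanines separated by short loops),
    intersects the hits with gene-regulatory features (TSS, UTRs, exons,
    introns, splice-site windows), EST transcription start records and
    mutation catalogs, and computes the associated enrichment statistics
    (Fisher 2x2 tests, enrichment factors), expression-level and
    coefficient-of-variation statistics (indiv-CV, g-CV, paired
    tumor/normal tests), mutation hotspot rankings with stability-score
    stratification, and a 500-bp hairpin folding free-energy landscape via
    a pluggable folding adapter.  A seeded synthetic-data generator with
    planted ground truth makes every stage runnable and testable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
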