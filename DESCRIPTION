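Package: kanseek
Title: Identification of Transcription-Factor Direct Targets from ChIP
    Enrichment and Induction Time-Course Expression
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for calling direct targets of an
    inducible transcription factor. Filters ChIP-enriched regions by
    replicate fold enrichment, scans them for a degenerate IUPAC
    binding motif on both strands, annotates regions to gene models
    with a strand-aware upstream/downstream/in-CDS label and a
    summit-to-CDS distance, calls per-gene transcriptional
    down-regulation from probe-level induction time courses, and
    intersects the binding and expression evidence into direct-target
    tables. A second factor's binding sites can be compared per gene
    for proximal co-binding. A fully specified synthetic-study
    generator (genome, gene models, planted motif instances, enriched
    regions, probe tracks) with recorded ground truth makes every
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
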