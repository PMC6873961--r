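Package: panelmips
Title: Clinical Cancer Panel Design and Single-Molecule MIP Consensus
    Variant Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Designs targeted cancer capture panels from a clinical variant
    knowledgebase snapshot (evidence scoring, sequence-ontology eligibility,
    hotspot versus exon-tiling strategy assignment, merged BED targets),
    collapses molecular-tagged (smMIP/UMI) reads into single-molecule
    consensus pileups, calls variants with allele frequencies, validates
    them against orthogonal sequencing (sensitivity and VAF concordance),
    classifies panel-only variants into germline, repeat-context artifact,
    insufficient-coverage (exact binomial detectability test) or
    low-support categories, and renders clinical annotation reports by
    exact coordinate matching back to the knowledgebase. Includes a
    seed-deterministic synthetic-data generator emulating a tumor/normal
    validation cohort so every stage can be exercised without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    methods,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    Rsamtools
Config/testthat/edition: 3
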