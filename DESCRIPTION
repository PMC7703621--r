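Package: crosscaff
Title: Homology-Based Iterative Scaffolding of Draft Genome Assemblies
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Improves two draft genome assemblies of the same species by
    mutual, iterative scaffolding: error-free mate-pair libraries over a
    ladder of insert sizes are simulated from one draft, placed on the
    other with a seed-and-extend matcher, filtered to confident concordant
    pairs, and aggregated into link bundles that drive a greedy
    super-scaffolding step; the two drafts alternate roles until their
    contiguity (N50/L50) stops improving. A companion module anchors
    physical-map markers to the scaffolds, assigns scaffolds to chromosome
    arms with conflict resolution, orients and orders them by marker rank,
    and stitches chromosome-scale pseudomolecules with 1000-N spacers,
    emitting FASTA and AGP 2.0. A synthetic two-strain fixture generator
    with truth tables supports end-to-end validation and recovery scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
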