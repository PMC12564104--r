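Package: plastedit
Title: Discovery of Plastid RNA Editing Sites from Strand-Specific RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for identifying C-to-U (and rare U-to-C) RNA editing
    sites in plant plastomes from strand-specific RNA-seq pileups. Implements
    strand-aware candidate calling under read-support and variant-allele-
    fraction thresholds, a four-class technical-artifact filter (splice-
    junction misalignment, dUTP second-strand carryover, rRNA modification
    misincorporation, strand misassignment), codon-level annotation of edits
    on spliced coding sequences, and cross-sample/cross-library
    reproducibility synthesis into a high-confidence editing-site set. A
    synthetic-data generator emulates the signal and artifact structure of
    total, rRNA-depleted and poly(A) libraries so the full pipeline is
    testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
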